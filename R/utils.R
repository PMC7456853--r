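#' Canonicalize a nucleotide sequence to uppercase RNA
#'
#' Uppercases and converts T to U. Accepts vectors. Characters outside
#' `A`, `C`, `G`, `U`, `T`, `N` (after case folding) are rejected.
#'
#' @param x character vector of sequences.
#' @return character vector of canonical RNA sequences.
#' @export
canonicalize_rna <- function(x) {
  out <- chartr("T", "U", toupper(x))
  bad <- grepl("[^ACGUN]", out)
  if (any(bad)) {
    abort(sprintf("sequence %d contains characters outside A/C/G/U/T/N",
                  which(bad)[1]))
  }
  out
}

#' Reverse complement of an RNA sequence
#'
#' @param x character vector of canonical RNA sequences.
#' @return character vector of reverse complements (RNA alphabet).
#' @export
reverse_complement <- function(x) {
  comp <- chartr("ACGUN", "UGCAN", canonicalize_rna(x))
  vapply(strsplit(comp, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1))
}

# integer encoding used by the C++ kernels: A=0, C=1, G=2, U=3
encode_rna <- function(seq) {
  m <- match(strsplit(seq, "", fixed = TRUE)[[1]], c("A", "C", "G", "U"))
  if (anyNA(m)) abort("sequence contains N or non-RNA characters; cannot scan")
  m - 1L
}

# deterministic sub-seed derivation: keeps seeds valid 32-bit integers and
# makes each pipeline stage reproducible in isolation
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 48271 + offset) %% 2147483647)
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}
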