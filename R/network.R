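#' Construct a miRNA-protein regulatory network object
#'
#' A bipartite graph: miRNA nodes on one side, protein nodes on the other,
#' with an edge only where the two endpoints changed in opposite directions
#' after treatment (the inverse-correlation rule).  Isolated nodes are not
#' allowed; every node carries its fold change and direction.
#'
#' @param nodes tibble with columns `id`, `kind` (`"miRNA"`/`"protein"`),
#'   `fc`, `direction`.
#' @param edges tibble with columns `mirna_id`, `protein_id` and optionally
#'   `score` (scanner evidence; `NA` when edges come from a published pair
#'   table).
#' @return a `regulatory_network` object.
#' @export
regulatory_network <- function(nodes, edges) {
  nodes <- as_tibble(nodes)
  edges <- as_tibble(edges)
  if (!"score" %in% names(edges)) edges$score <- NA_integer_
  stopifnot(all(c("id", "kind", "fc", "direction") %in% names(nodes)),
            all(c("mirna_id", "protein_id") %in% names(edges)))
  if (any(nodes$fc <= 0)) abort("node fold changes must be positive")
  mir_ids <- nodes$id[nodes$kind == "miRNA"]
  prot_ids <- nodes$id[nodes$kind == "protein"]
  if (!all(edges$mirna_id %in% mir_ids) ||
      !all(edges$protein_id %in% prot_ids)) {
    abort("edge endpoint missing from nodes or on the wrong side (bipartite violation)")
  }
  deg <- c(edges$mirna_id, edges$protein_id)
  if (!all(nodes$id %in% deg)) abort("isolated node in network")
  dir_of <- setNames(nodes$direction, nodes$id)
  opp <- (dir_of[edges$mirna_id] == "up" & dir_of[edges$protein_id] == "down") |
         (dir_of[edges$mirna_id] == "down" & dir_of[edges$protein_id] == "up")
  if (nrow(edges) > 0 && !all(opp)) {
    abort("edge violates the inverse-direction invariant")
  }
  structure(list(nodes = nodes, edges = edges), class = "regulatory_network")
}

empty_network <- function() {
  regulatory_network(
    tibble(id = character(), kind = character(), fc = numeric(),
           direction = character()),
    tibble(mirna_id = character(), protein_id = character(),
           score = integer()))
}

#' Build the regulatory network from differential-expression calls and a
#' target map
#'
#' An edge (miRNA m, protein p) is included if and only if m is a
#' significant DE miRNA, p a significant DE protein, p's 3'UTR is a
#' predicted target of m, and the two log2 fold changes have opposite sign.
#' Nodes are exactly the endpoints of included edges.
#'
#' @param de_mirnas miRNA DE results (from [call_de_mirnas()]).
#' @param de_proteins protein DE results (from [call_de_proteins()]).
#' @param target_map hit tibble with `mirna_id`, `utr_id`, `score` (from
#'   [scan_targets()]).
#' @param id_map optional tibble mapping `protein_id` to `utr_id`; by
#'   default protein ids are assumed to equal UTR ids.
#' @return a [regulatory_network()].
#' @export
build_network <- function(de_mirnas, de_proteins, target_map, id_map = NULL) {
  sig_m <- de_mirnas[de_mirnas$significant, , drop = FALSE]
  sig_p <- de_proteins[de_proteins$significant, , drop = FALSE]
  if (length(intersect(sig_m$mirna_id, sig_p$protein_id))) {
    abort("miRNA and protein identifier namespaces collide")
  }
  if (nrow(sig_m) == 0 || nrow(sig_p) == 0 || nrow(target_map) == 0) {
    return(empty_network())
  }
  id_map <- id_map %||% tibble(protein_id = sig_p$protein_id,
                               utr_id = sig_p$protein_id)
  edges <- sig_p |>
    dplyr::select("protein_id", p_log2fc = "log2fc", p_fc = "fc") |>
    dplyr::inner_join(id_map, by = "protein_id") |>
    dplyr::inner_join(
      dplyr::select(target_map, "mirna_id", "utr_id", "score"),
      by = "utr_id", relationship = "many-to-many") |>
    dplyr::inner_join(
      dplyr::select(sig_m, "mirna_id", m_log2fc = "log2fc", m_fc = "fc"),
      by = "mirna_id") |>
    dplyr::filter(sign(.data$m_log2fc) * sign(.data$p_log2fc) < 0) |>
    dplyr::arrange(.data$mirna_id, .data$protein_id)
  if (nrow(edges) == 0) return(empty_network())
  nodes <- dplyr::bind_rows(
    edges |>
      dplyr::distinct(id = .data$mirna_id, fc = .data$m_fc) |>
      dplyr::mutate(kind = "miRNA"),
    edges |>
      dplyr::distinct(id = .data$protein_id, fc = .data$p_fc) |>
      dplyr::mutate(kind = "protein")) |>
    dplyr::mutate(direction = ifelse(.data$fc > 1, "up", "down")) |>
    dplyr::select("id", "kind", "fc", "direction")
  regulatory_network(nodes,
                     edges[, c("mirna_id", "protein_id", "score")])
}

#' Build a regulatory network from a published pair table
#'
#' One edge per row of a table shaped like the published miRNA/target-pair
#' listing (`mirna`, `mirna_fc`, `protein`, `protein_fc`).  Rows whose two
#' fold changes do not lie on opposite sides of 1 violate the inverse rule;
#' they are rejected and reported in the `rejected` attribute (with a
#' warning) rather than silently dropped.
#'
#' @param pairs tibble with columns `mirna`, `mirna_fc`, `protein`,
#'   `protein_fc`.
#' @return a [regulatory_network()] with attribute `rejected`.
#' @export
build_network_from_pairs <- function(pairs) {
  if (any(pairs$mirna_fc <= 0) || any(pairs$protein_fc <= 0)) {
    abort("fold changes must be positive")
  }
  bad <- sign(log(pairs$mirna_fc)) * sign(log(pairs$protein_fc)) >= 0
  rejected <- pairs[bad, , drop = FALSE]
  if (nrow(rejected) > 0) {
    warning(sprintf("%d pair(s) rejected for violating the inverse-direction rule",
                    nrow(rejected)), call. = FALSE)
  }
  pairs <- pairs[!bad, , drop = FALSE]
  if (nrow(pairs) == 0) {
    net <- empty_network()
    attr(net, "rejected") <- rejected
    return(net)
  }
  nodes <- dplyr::bind_rows(
    pairs |> dplyr::distinct(id = .data$mirna, fc = .data$mirna_fc) |>
      dplyr::mutate(kind = "miRNA"),
    pairs |> dplyr::distinct(id = .data$protein, fc = .data$protein_fc) |>
      dplyr::mutate(kind = "protein")) |>
    dplyr::mutate(direction = ifelse(.data$fc > 1, "up", "down")) |>
    dplyr::select("id", "kind", "fc", "direction")
  net <- regulatory_network(
    nodes, tibble(mirna_id = pairs$mirna, protein_id = pairs$protein,
                  score = NA_integer_))
  attr(net, "rejected") <- rejected
  net
}

#' Summary statistics of a regulatory network
#'
#' @param net a [regulatory_network()].
#' @return a list with `n_mirnas`, `n_proteins`, `n_edges`, a `degree`
#'   tibble, and the extremal fold changes per node kind.
#' @export
network_stats <- function(net) {
  nodes <- net$nodes; edges <- net$edges
  deg <- table(factor(c(edges$mirna_id, edges$protein_id),
                      levels = nodes$id))
  mir <- nodes[nodes$kind == "miRNA", , drop = FALSE]
  prot <- nodes[nodes$kind == "protein", , drop = FALSE]
  rng <- function(x) if (length(x)) range(x) else c(NA_real_, NA_real_)
  list(n_mirnas = nrow(mir), n_proteins = nrow(prot), n_edges = nrow(edges),
       degree = tibble(id = nodes$id, kind = nodes$kind,
                       degree = as.integer(deg[nodes$id])),
       mirna_fc_range = rng(mir$fc), protein_fc_range = rng(prot$fc))
}

#' Precision and recall of a predicted edge set against planted truth
#'
#' @param predicted tibble with `mirna_id`, `protein_id` (e.g. the edges of
#'   a built network).
#' @param truth tibble with the planted `mirna_id`, `protein_id` edges.
#' @return a one-row tibble with `n_predicted`, `n_true`, `tp`, `precision`,
#'   `recall`.
#' @export
edge_metrics <- function(predicted, truth) {
  key <- function(d) paste(d$mirna_id, d$protein_id, sep = "\r")
  tp <- length(intersect(key(predicted), key(truth)))
  tibble(n_predicted = nrow(predicted), n_true = nrow(truth), tp = tp,
         precision = if (nrow(predicted)) tp / nrow(predicted) else NA_real_,
         recall = if (nrow(truth)) tp / nrow(truth) else NA_real_)
}

#' @export
print.regulatory_network <- function(x, ...) {
  s <- network_stats(x)
  cat(sprintf("miRNA-protein regulatory network: %d miRNAs, %d proteins, %d edges\n",
              s$n_mirnas, s$n_proteins, s$n_edges))
  invisible(x)
}

#' @rdname regulatory_network
#' @param x a `regulatory_network`.
#' @param ... unused.
#' @export
tidy.regulatory_network <- function(x, ...) {
  fc_of <- setNames(x$nodes$fc, x$nodes$id)
  tibble(mirna = x$edges$mirna_id,
         mirna_fc = unname(fc_of[x$edges$mirna_id]),
         protein = x$edges$protein_id,
         protein_fc = unname(fc_of[x$edges$protein_id]),
         score = x$edges$score)
}

#' @rdname regulatory_network
#' @export
glance.regulatory_network <- function(x, ...) {
  s <- network_stats(x)
  tibble(n_mirnas = s$n_mirnas, n_proteins = s$n_proteins,
         n_edges = s$n_edges,
         min_mirna_fc = s$mirna_fc_range[1], max_mirna_fc = s$mirna_fc_range[2],
         min_protein_fc = s$protein_fc_range[1],
         max_protein_fc = s$protein_fc_range[2])
}

as_igraph <- function(net) {
  g <- igraph::graph_from_data_frame(
    d = data.frame(from = net$edges$mirna_id, to = net$edges$protein_id,
                   score = ifelse(is.na(net$edges$score), -1L, net$edges$score)),
    directed = FALSE,
    vertices = data.frame(name = net$nodes$id, kind = net$nodes$kind,
                          fc = net$nodes$fc, direction = net$nodes$direction))
  g
}

#' Serialize a regulatory network
#'
#' @param net a [regulatory_network()].
#' @param path output path.
#' @param format `"tsv"` (edge list with node fold changes), `"sif"`, or
#'   `"graphml"`.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path, format = c("tsv", "sif", "graphml")) {
  format <- match.arg(format)
  if (format == "tsv") {
    readr::write_tsv(tidy(net), path, progress = FALSE)
  } else if (format == "sif") {
    writeLines(sprintf("%s\ttargets\t%s", net$edges$mirna_id,
                       net$edges$protein_id), path)
  } else {
    igraph::write_graph(as_igraph(net), path, format = "graphml")
  }
  invisible(path)
}

#' Read a regulatory network written by [write_network()]
#'
#' Supports the `tsv` and `graphml` formats (SIF drops node attributes and
#' cannot be round-tripped).
#'
#' @param path input path.
#' @param format `"tsv"` or `"graphml"`.
#' @return a [regulatory_network()].
#' @export
read_network <- function(path, format = c("tsv", "graphml")) {
  format <- match.arg(format)
  if (format == "tsv") {
    d <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
    net <- build_network_from_pairs(
      tibble(mirna = d$mirna, mirna_fc = d$mirna_fc,
             protein = d$protein, protein_fc = d$protein_fc))
    net$edges$score <- d$score
    return(net)
  }
  g <- igraph::read_graph(path, format = "graphml")
  v <- igraph::as_data_frame(g, "vertices")
  e <- igraph::as_data_frame(g, "edges")
  nodes <- tibble(id = v$name, kind = v$kind, fc = v$fc,
                  direction = v$direction)
  kind_of <- setNames(nodes$kind, nodes$id)
  mirna_id <- ifelse(kind_of[e$from] == "miRNA", e$from, e$to)
  protein_id <- ifelse(kind_of[e$from] == "miRNA", e$to, e$from)
  score <- if (nrow(e)) as.integer(ifelse(e$score < 0, NA, e$score)) else integer()
  regulatory_network(nodes, tibble(mirna_id = mirna_id,
                                   protein_id = protein_id, score = score))
}
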