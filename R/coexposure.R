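#' Pairwise exposure correlation matrix
#'
#' Pearson correlations between pesticides' transformed exposures at one
#' location type, pairwise-complete over participants. Zero-variance
#' pesticides get missing rows/columns and a message.
#'
#' @param exposure Long exposure tibble with `participant_id`,
#'   `location_type`, `pesticide_id` and the value column.
#' @param pesticide_ids Pesticides to include (e.g. the implicated set);
#'   default all.
#' @param location Location type of the exposure layer.
#' @param value Column to correlate: `"z"` (transformed, the default) or
#'   `"raw"`.
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
exposure_corr <- function(exposure, pesticide_ids = NULL,
                          location = "residential", value = "z") {
  dat <- exposure %>% filter(.data$location_type == location)
  if (!is.null(pesticide_ids)) {
    dat <- dat %>% filter(.data$pesticide_id %in% pesticide_ids)
  }
  wide <- dat %>%
    select("participant_id", "pesticide_id", dplyr::all_of(value)) %>%
    tidyr::pivot_wider(names_from = "pesticide_id",
                       values_from = dplyr::all_of(value)) %>%
    select(-"participant_id")
  wide <- wide[, sort(names(wide)), drop = FALSE]
  novar <- vapply(wide, function(x) sd(x, na.rm = TRUE) == 0 ||
                    all(is.na(x)), logical(1))
  if (any(novar)) {
    inform(sprintf("zero-variance pesticide(s) set to NA: %s",
                   paste(names(wide)[novar], collapse = ", ")))
  }
  r <- suppressWarnings(
    cor(as.matrix(wide), use = "pairwise.complete.obs", method = "pearson")
  )
  r[novar, ] <- NA
  r[, novar] <- NA
  diag(r) <- 1
  r
}

#' Two-layer co-exposure network
#'
#' Builds the cross-layer correlation network between directly neurotoxic
#' pesticides and the remaining implicated pesticides: an edge joins a
#' toxic and a non-toxic pesticide when their exposure correlation exceeds
#' the threshold; within-layer correlations are not drawn. Nodes are
#' ordered by descending cross-layer degree (lexical tie-break), closeness
#' centrality is computed on the retained (unweighted) graph, and the
#' summary statistic is the fraction of non-toxic pesticides linked to at
#' least one toxic pesticide.
#'
#' @param r Correlation matrix from [exposure_corr()].
#' @param toxic Character vector of directly toxic pesticide ids (subset of
#'   the matrix ids; must be non-empty).
#' @param threshold Correlation threshold for an edge (edges require
#'   R > threshold).
#' @return A `coexposure_graph`: list with `nodes` (id, layer, degree,
#'   closeness, in descending degree order), `edges` (from = toxic,
#'   to = other, weight = R), `graph` (igraph object over nodes with >= 1
#'   edge), `linked_fraction`, `threshold`.
#' @export
build_network <- function(r, toxic, threshold = 0.45) {
  ids <- rownames(r)
  if (length(toxic) == 0) abort("toxic set must be non-empty.")
  if (!all(toxic %in% ids)) {
    abort("toxic set must be a subset of the correlation matrix ids.")
  }
  other <- setdiff(ids, toxic)
  edges <- tidyr::crossing(from = intersect(toxic, ids), to = other) %>%
    mutate(weight = r[cbind(.data$from, .data$to)]) %>%
    filter(!is.na(.data$weight), .data$weight > threshold)
  g <- igraph::graph_from_data_frame(
    edges, directed = FALSE,
    vertices = tibble(name = ids, layer = ifelse(ids %in% toxic,
                                                 "mDA-toxic", "other"))
  )
  deg <- igraph::degree(g)
  retained <- igraph::induced_subgraph(g, igraph::V(g)[deg > 0])
  clo <- rep(NA_real_, length(ids)); names(clo) <- ids
  if (igraph::vcount(retained) > 0) {
    clo[igraph::V(retained)$name] <-
      suppressWarnings(igraph::closeness(retained, normalized = TRUE))
  }
  nodes <- tibble(
    pesticide_id = ids,
    layer = ifelse(ids %in% toxic, "mDA-toxic", "other"),
    degree = unname(deg[ids]),
    closeness = unname(clo[ids])
  ) %>%
    arrange(dplyr::desc(.data$degree), .data$pesticide_id)
  linked <- if (length(other) == 0) NA_real_ else {
    mean(other %in% edges$to)
  }
  structure(list(
    nodes = nodes, edges = edges, graph = retained,
    linked_fraction = linked, threshold = threshold
  ), class = "coexposure_graph")
}

#' @export
print.coexposure_graph <- function(x, ...) {
  cat(sprintf(
    "<coexposure_graph> %d nodes, %d cross-layer edges at R > %.2f; %.0f%% of non-toxic pesticides linked to a toxic one\n",
    nrow(x$nodes), nrow(x$edges), x$threshold, 100 * x$linked_fraction
  ))
  print(x$nodes, ...)
  invisible(x)
}

#' Co-exposure clusters by hierarchical clustering
#'
#' Agglomerative clustering of pesticides on distance `1 - R`, cut at the
#' given height. With complete linkage (the default) a cut at 0.55
#' guarantees all within-cluster pairwise correlations exceed 0.45,
#' matching the network threshold; average linkage is selectable. Cluster
#' labels are deterministic: numbered by decreasing size, ties broken by
#' the lexically smallest member.
#'
#' @param r Complete correlation matrix (no missing entries).
#' @param height Cut height on the `1 - R` scale.
#' @param method Linkage: `"complete"` (default) or `"average"`.
#' @return Tibble `pesticide_id`, `cluster` (integer), with the `hclust`
#'   tree attached as attribute `"tree"`.
#' @export
cluster_exposures <- function(r, height = 0.55,
                              method = c("complete", "average")) {
  method <- match.arg(method)
  if (anyNA(r)) {
    abort(paste(
      "correlation matrix has missing entries;",
      "recompute with pairwise-complete observations or drop",
      "zero-variance pesticides first."
    ))
  }
  d <- as.dist(1 - r)
  tree <- hclust(d, method = method)
  raw <- cutree(tree, h = height)
  sizes <- table(raw)
  first_member <- tapply(names(raw), raw, function(x) min(x))
  ord <- order(-as.integer(sizes), first_member)
  relabel <- setNames(seq_along(ord), names(sizes)[ord])
  out <- tibble(
    pesticide_id = names(raw),
    cluster = unname(relabel[as.character(raw)])
  ) %>%
    arrange(.data$cluster, .data$pesticide_id)
  attr(out, "tree") <- tree
  attr(out, "height") <- height
  out
}

#' Share of a pesticide's application records on a crop
#'
#' Proportion of all application records for each pesticide that were on
#' the given crop, over the supplied region/period of records — the
#' statistic that identifies crop-anchored co-exposure clusters (defoliant
#' use is almost exclusively on cotton).
#'
#' @param applications Application records with `pesticide_id` and `crop`.
#' @param crop Crop of interest.
#' @param pesticide_ids Optional subset; pesticides with no records yield
#'   an NA share and a message.
#' @return Tibble: `pesticide_id`, `n_records`, `n_on_crop`, `share`.
#' @export
share_on_crop <- function(applications, crop = "cotton",
                          pesticide_ids = NULL) {
  tab <- applications %>%
    group_by(.data$pesticide_id) %>%
    summarise(
      n_records = dplyr::n(),
      n_on_crop = sum(.data$crop == .env$crop),
      .groups = "drop"
    ) %>%
    mutate(share = .data$n_on_crop / .data$n_records)
  if (!is.null(pesticide_ids)) {
    missing <- setdiff(pesticide_ids, tab$pesticide_id)
    if (length(missing) > 0) {
      inform(sprintf("no application records for: %s",
                     paste(missing, collapse = ", ")))
    }
    tab <- tibble(pesticide_id = pesticide_ids) %>%
      left_join(tab, by = "pesticide_id")
  }
  tab %>% arrange(dplyr::desc(.data$share))
}
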