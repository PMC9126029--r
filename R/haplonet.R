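## Median-joining networks over unique haplotypes within a selection signal,
## the favourable-haplotype group, and ancestral/derived classification of
## the swept haplotype against outgroup haplotypes.

#' Collapse haplotypes into unique nodes with per-population counts
#'
#' Identical haplotype strings are merged; each node records its total count
#' and a per-population count vector. Haplotypes with missing calls inside
#' the window are excluded with a warning (exact haplotypes are required).
#'
#' @param haps a [phased_haplotypes()] or 0/1 matrix (haplotypes x SNPs).
#' @param populations population label per haplotype (defaults to the
#'   `population` column of the haplotype metadata).
#' @param outgroup logical per haplotype (defaults to `species ==
#'   "outgroup"` from the metadata; `FALSE` everywhere when unavailable).
#' @param window optional `c(first, last)` SNP column range to restrict to.
#' @return An object of class `haplo_nodes`: list with `hap` (node x SNP 0/1
#'   matrix), `count`, `pop_counts` (node x population matrix),
#'   `outgroup_count` per node.
#' @export
unique_haplotypes <- function(haps, populations = NULL, outgroup = NULL,
                              window = NULL) {
  H <- if (inherits(haps, "phased_haplotypes")) haps$haps else as.matrix(haps)
  meta <- if (inherits(haps, "phased_haplotypes")) haps$meta else NULL
  if (is.null(populations)) {
    populations <- if (!is.null(meta)) meta$population else
      rep("pop1", nrow(H))
  }
  if (is.null(outgroup)) {
    outgroup <- if (!is.null(meta)) meta$species == "outgroup" else
      rep(FALSE, nrow(H))
  }
  if (!is.null(window)) H <- H[, window[1]:window[2], drop = FALSE]
  has_na <- rowSums(is.na(H)) > 0
  if (any(has_na)) {
    warning(sum(has_na), " haplotype(s) with missing calls excluded")
    H <- H[!has_na, , drop = FALSE]
    populations <- populations[!has_na]
    outgroup <- outgroup[!has_na]
  }
  if (nrow(H) == 0) stop("no complete haplotypes in window")
  key <- apply(H, 1, paste, collapse = "")
  uniq <- !duplicated(key)
  node_of <- match(key, key[uniq])
  n_nodes <- sum(uniq)
  pops <- sort(unique(populations))
  pop_counts <- matrix(0L, n_nodes, length(pops), dimnames = list(NULL, pops))
  og_count <- integer(n_nodes)
  for (r in seq_along(node_of)) {
    pop_counts[node_of[r], populations[r]] <- pop_counts[node_of[r], populations[r]] + 1L
    if (outgroup[r]) og_count[node_of[r]] <- og_count[node_of[r]] + 1L
  }
  structure(list(hap = H[uniq, , drop = FALSE],
                 count = as.integer(tabulate(node_of, n_nodes)),
                 pop_counts = pop_counts,
                 outgroup_count = og_count),
            class = "haplo_nodes")
}

hamming_matrix <- function(H) {
  d <- as.matrix(stats::dist(H, method = "manhattan"))
  dimnames(d) <- NULL
  d
}

## Minimum spanning network: process pairwise distances level by level;
## at each distance level, add every pair whose endpoints lie in different
## connected components as assessed BEFORE the level, then merge.
min_spanning_network <- function(d, epsilon = 0) {
  n <- nrow(d)
  if (n == 1) return(data.frame(from = integer(), to = integer(), weight = numeric()))
  comp <- seq_len(n)
  edges <- list()
  for (w in sort(unique(d[upper.tri(d)]))) {
    pairs <- which(upper.tri(d) & abs(d - w) <= epsilon & d >= w, arr.ind = TRUE)
    snapshot <- comp
    added <- FALSE
    for (r in seq_len(nrow(pairs))) {
      i <- pairs[r, 1]; j <- pairs[r, 2]
      if (snapshot[i] != snapshot[j]) {
        edges[[length(edges) + 1]] <- c(i, j, d[i, j])
        comp[comp == comp[j]] <- comp[i]
        added <- TRUE
      }
    }
    if (length(unique(comp)) == 1) break
  }
  e <- do.call(rbind, edges)
  data.frame(from = as.integer(e[, 1]), to = as.integer(e[, 2]),
             weight = e[, 3])
}

#' Median-joining network of unique haplotypes
#'
#' Builds a minimum-spanning network over observed haplotypes, then
#' iteratively proposes median (consensus) vectors for triplets linked in
#' the current network and accepts any new median whose summed distance to
#' the triplet is below the triplet's minimum-spanning cost (within
#' `epsilon`); obsolete medians (degree <= 2 in the final network) are
#' pruned. When no feasible median exists the result is exactly the
#' minimum-spanning network. Edge weights are Hamming distances.
#'
#' @param nodes a `haplo_nodes` object from [unique_haplotypes()].
#' @param epsilon cost tolerance for accepting medians (default 0).
#' @param max_rounds safety cap on median-addition rounds.
#' @return An object of class `haplo_network`: `nodes` (with medians
#'   appended, `is_median` flag), `edges` (`from`, `to`, `weight`), and an
#'   igraph `graph`.
#' @export
median_joining_network <- function(nodes, epsilon = 0, max_rounds = 20) {
  if (!inherits(nodes, "haplo_nodes")) stop("nodes must come from unique_haplotypes")
  H <- nodes$hap
  n_obs <- nrow(H)
  if (n_obs < 1) stop("need at least one haplotype")
  is_median <- rep(FALSE, n_obs)
  for (round in seq_len(max_rounds)) {
    d <- hamming_matrix(H)
    net <- min_spanning_network(d, epsilon = 0)
    if (nrow(net) == 0) break
    adj <- matrix(FALSE, nrow(H), nrow(H))
    adj[cbind(net$from, net$to)] <- TRUE
    adj <- adj | t(adj)
    new_meds <- list()
    ## triplets forming a path of length 2 in the current network
    for (v in seq_len(nrow(H))) {
      nb <- which(adj[v, ])
      if (length(nb) < 2) next
      cmb <- utils::combn(nb, 2)
      for (k in seq_len(ncol(cmb))) {
        u <- cmb[1, k]; w <- cmb[2, k]
        trip <- H[c(u, v, w), , drop = FALSE]
        med <- as.integer(colSums(trip) >= 2)
        cost <- sum(abs(sweep(trip, 2, med)))
        tri <- c(d[u, v], d[v, w], d[u, w])
        mst_cost <- sum(tri) - max(tri)
        if (cost < mst_cost + epsilon + 1e-9) {
          new_meds[[length(new_meds) + 1]] <- med
        }
      }
    }
    if (length(new_meds) == 0) break
    M <- unique(do.call(rbind, new_meds))
    key_old <- apply(H, 1, paste, collapse = "")
    key_new <- apply(M, 1, paste, collapse = "")
    fresh <- !(key_new %in% key_old)
    if (!any(fresh)) break
    H <- rbind(H, M[fresh, , drop = FALSE])
    is_median <- c(is_median, rep(TRUE, sum(fresh)))
  }
  ## final network; prune median vectors that end up as pass-through or
  ## dangling nodes (degree <= 2), reconnecting via a fresh MSN
  repeat {
    d <- hamming_matrix(H)
    net <- min_spanning_network(d, epsilon = 0)
    deg <- tabulate(c(net$from, net$to), nrow(H))
    drop <- is_median & deg <= 2
    if (!any(drop)) break
    H <- H[!drop, , drop = FALSE]
    is_median <- is_median[!drop]
  }
  count <- c(nodes$count, rep(0L, sum(is_median)))
  pop_counts <- rbind(nodes$pop_counts,
                      matrix(0L, sum(is_median), ncol(nodes$pop_counts)))
  og <- c(nodes$outgroup_count, rep(0L, sum(is_median)))
  g <- igraph::graph_from_data_frame(
    data.frame(from = net$from, to = net$to, weight = net$weight),
    directed = FALSE,
    vertices = data.frame(name = seq_len(nrow(H)), count = count,
                          is_median = is_median))
  structure(list(hap = H, count = count, pop_counts = pop_counts,
                 outgroup_count = og, is_median = is_median,
                 edges = net, graph = g),
            class = "haplo_network")
}

#' @exportS3Method base::print
print.haplo_network <- function(x, ...) {
  cat("haplo_network:", sum(!x$is_median), "observed +", sum(x$is_median),
      "median nodes,", nrow(x$edges), "edges\n")
  invisible(x)
}

## Shortest-path mutation distances between nodes through the network.
network_distances <- function(net) {
  igraph::distances(net$graph, weights = igraph::E(net$graph)$weight)
}

#' Favourable-haplotype group around the most common haplotype
#'
#' The group holds the most frequent observed haplotype (counted over focal,
#' non-outgroup samples) plus every observed
#' haplotype within `max_mutations` of it. Distance is the shortest-path
#' mutation distance through the network by default (median nodes may lie on
#' the path); `use_path = FALSE` uses raw Hamming distance instead. Ties for
#' the most frequent node all seed the group (their union), flagged via the
#' `"tied_seed"` attribute.
#'
#' @param net a `haplo_network`.
#' @param max_mutations maximum mutation distance from a seed (default 3).
#' @param use_path shortest-path (`TRUE`) or Hamming (`FALSE`) distance.
#' @return Integer vector of node indices in the group, with attribute
#'   `"seed"` (and `"tied_seed"` flag).
#' @export
favourable_group <- function(net, max_mutations = 3, use_path = TRUE) {
  obs <- which(!net$is_median)
  focal <- net$count - net$outgroup_count
  mx <- max(focal[obs])
  seeds <- obs[focal[obs] == mx]
  D <- if (use_path) network_distances(net) else hamming_matrix(net$hap)
  dmin <- apply(D[seeds, , drop = FALSE], 2, min)
  group <- obs[dmin[obs] <= max_mutations]
  attr(group, "seed") <- seeds
  attr(group, "tied_seed") <- length(seeds) > 1
  group
}

#' Classify the selected haplotype as ancestral or derived
#'
#' If the most common outgroup haplotype falls inside the favourable group,
#' the selected haplotype is classified `"ancestral"` (selection acts on the
#' state carried by the outgroup); if it falls outside, `"derived"`. When
#' tied outgroup-major haplotypes span both sides, the call is
#' `"ambiguous"`.
#'
#' @param net a `haplo_network` containing outgroup haplotypes.
#' @param group node indices from [favourable_group()].
#' @return `"ancestral"`, `"derived"` or `"ambiguous"`, with attribute
#'   `"outgroup_major"` giving the node index/indices.
#' @export
classify_origin <- function(net, group) {
  if (sum(net$outgroup_count) == 0) stop("no outgroup haplotypes in network")
  mx <- max(net$outgroup_count)
  major <- which(net$outgroup_count == mx)
  inside <- major %in% group
  res <- if (all(inside)) "ancestral" else if (!any(inside)) "derived" else "ambiguous"
  attr(res, "outgroup_major") <- major
  res
}

#' Per-population shares within the favourable group
#'
#' For each population, the share of its haplotypes that fall on nodes of
#' the favourable group, plus the max/min share ratio as a one-number
#' evenness summary (1 = perfectly even participation across populations).
#'
#' @param net a `haplo_network`.
#' @param group node indices from [favourable_group()].
#' @return list with `shares` (named numeric) and `evenness_ratio`.
#' @export
breed_evenness <- function(net, group) {
  if (length(group) == 0) stop("empty favourable group")
  tot <- colSums(net$pop_counts)
  ing <- colSums(net$pop_counts[group, , drop = FALSE])
  keep <- tot > 0
  shares <- ing[keep] / tot[keep]
  list(shares = shares,
       evenness_ratio = if (min(shares) > 0) max(shares) / min(shares) else Inf)
}

#' Write a haplotype network to GML and TSV
#'
#' @param net a `haplo_network`.
#' @param prefix output path prefix; writes `<prefix>_network.gml`,
#'   `<prefix>_edges.tsv`, `<prefix>_nodes.tsv`.
#' @return Paths written, invisibly.
#' @export
write_haplonet <- function(net, prefix) {
  gml <- paste0(prefix, "_network.gml")
  igraph::write_graph(net$graph, gml, format = "gml")
  edges <- paste0(prefix, "_edges.tsv")
  write_tsv(net$edges, edges)
  nodes <- paste0(prefix, "_nodes.tsv")
  nd <- data.frame(node = seq_along(net$count), count = net$count,
                   is_median = net$is_median,
                   outgroup_count = net$outgroup_count,
                   haplotype = apply(net$hap, 1, paste, collapse = ""))
  nd <- cbind(nd, as.data.frame(net$pop_counts))
  write_tsv(nd, nodes)
  invisible(c(gml, edges, nodes))
}

#' Export haplotype sequences as a Nexus file
#'
#' Writes the window's unique haplotypes as binary sequences for external
#' network viewers; counts are appended to taxon labels.
#'
#' @param nodes a `haplo_nodes` object.
#' @param path output file.
#' @return The path, invisibly.
#' @export
write_nexus_haplotypes <- function(nodes, path) {
  H <- nodes$hap
  labels <- sprintf("hap%d_n%d", seq_len(nrow(H)), nodes$count)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("#NEXUS", "BEGIN DATA;",
               sprintf("DIMENSIONS NTAX=%d NCHAR=%d;", nrow(H), ncol(H)),
               "FORMAT DATATYPE=STANDARD SYMBOLS=\"01\" MISSING=?;",
               "MATRIX"), con)
  writeLines(paste(labels, apply(H, 1, paste, collapse = "")), con)
  writeLines(c(";", "END;"), con)
  invisible(path)
}
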