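#' Multi-IBD cluster detection
#'
#' Groups pairwise IBD segments into haplotypes shared by three or more
#' haplotype copies. The chromosome is tiled into windows; in each window a
#' graph over haplotype copies is built with an edge for every pairwise
#' segment covering the window, and connected components of at least
#' `min_copies` copies define window-clusters. Maximal runs of adjacent
#' windows with identical component membership are merged; the cluster
#' interval is the merged window span intersected with every supporting
#' segment, so each member pair's segment covers the full cluster interval.
#' Transitive (connected-component) grouping is the default, matching
#' multi-way IBD tools; `require_clique = TRUE` gives the stricter
#' all-pairs alternative.
#'
#' @param segments segment data.frame from [pairwise_ibd()], one chromosome.
#' @param min_copies minimum haplotype copies per cluster.
#' @param window_bp tiling window size.
#' @param require_clique demand a pairwise segment between every member
#'   pair, not just connectivity.
#' @return list of clusters; each is a list with `chrom`, `start`, `end`,
#'   `members` (data.frame `id`, `hap`), `carriers` (unique ids) and
#'   `support` (row indices of supporting segments).
#' @export
multi_ibd_clusters <- function(segments, min_copies = 3L, window_bp = 250000L,
                               require_clique = FALSE) {
  if (!nrow(segments)) return(list())
  if (length(unique(segments$chrom)) > 1)
    stop("segments from multiple chromosomes mixed; cluster one chromosome at a time")
  ch <- segments$chrom[1]
  key_a <- paste0(segments$id_a, ".", segments$hap_a)
  key_b <- paste0(segments$id_b, ".", segments$hap_b)
  lo <- min(segments$start); hi <- max(segments$end)
  edges <- seq(floor(lo / window_bp) * window_bp, hi, by = window_bp)
  win_start <- edges
  win_end <- edges + window_bp - 1

  members_per_window <- vector("list", length(win_start))
  for (w in seq_along(win_start)) {
    cov <- segments$start <= win_start[w] & segments$end >= win_end[w]
    if (!any(cov)) next
    verts <- unique(c(key_a[cov], key_b[cov]))
    g <- igraph::graph_from_data_frame(
      data.frame(from = key_a[cov], to = key_b[cov]),
      directed = FALSE, vertices = verts)
    comp <- igraph::components(g)
    for (cid in which(comp$csize >= min_copies)) {
      mem <- sort(names(comp$membership)[comp$membership == cid])
      if (require_clique) {
        pair_ok <- outer(mem, mem, function(x, y) {
          paste(pmin(x, y), pmax(x, y)) %in%
            paste(pmin(key_a[cov], key_b[cov]), pmax(key_a[cov], key_b[cov]))
        })
        if (!all(pair_ok[upper.tri(pair_ok)])) next
      }
      members_per_window[[w]] <- c(members_per_window[[w]],
                                   list(mem))
    }
  }

  # merge maximal runs of adjacent windows with identical membership
  clusters <- list()
  open <- list()  # signature -> list(first_w, last_w, members)
  sig_of <- function(mem) paste(mem, collapse = ";")
  for (w in seq_along(win_start)) {
    here <- members_per_window[[w]]
    here_sigs <- vapply(here, sig_of, character(1))
    for (sig in names(open)) {
      if (!(sig %in% here_sigs) || open[[sig]]$last_w != w - 1L) {
        clusters[[length(clusters) + 1L]] <- open[[sig]]
        open[[sig]] <- NULL
      }
    }
    for (k in seq_along(here)) {
      sig <- here_sigs[k]
      if (!is.null(open[[sig]]) && open[[sig]]$last_w == w - 1L) {
        open[[sig]]$last_w <- w
      } else if (is.null(open[[sig]])) {
        open[[sig]] <- list(first_w = w, last_w = w, members = here[[k]])
      }
    }
  }
  for (sig in names(open)) clusters[[length(clusters) + 1L]] <- open[[sig]]
  if (!length(clusters)) return(list())

  out <- list()
  seen <- character(0)
  for (cl in clusters) {
    mem <- cl$members
    span <- c(win_start[cl$first_w], win_end[cl$last_w])
    # clip the window span so every member pair's supporting segment covers
    # the final interval (per pair: the segment with maximal span overlap)
    pair_sup <- which((key_a %in% mem) & (key_b %in% mem))
    covering <- pair_sup[segments$start[pair_sup] <= span[2] &
                           segments$end[pair_sup] >= span[1]]
    pairs <- unique(paste(key_a[covering], key_b[covering]))
    start <- span[1]; end <- span[2]
    support <- integer(0)
    for (p in pairs) {
      rows <- covering[paste(key_a[covering], key_b[covering]) == p]
      ov <- pmin(segments$end[rows], span[2]) - pmax(segments$start[rows], span[1])
      best <- rows[which.max(ov)]
      support <- c(support, best)
      start <- max(start, segments$start[best])
      end <- min(end, segments$end[best])
    }
    if (end <= start) next
    md <- do.call(rbind, lapply(strsplit(mem, ".", fixed = TRUE), function(x)
      data.frame(id = paste(utils::head(x, -1), collapse = "."),
                 hap = as.integer(utils::tail(x, 1)))))
    sig <- paste(sig_of(mem), start, end)
    if (sig %in% seen) next
    seen <- c(seen, sig)
    out[[length(out) + 1L]] <- list(chrom = ch, start = start, end = end,
                                    members = md,
                                    carriers = sort(unique(md$id)),
                                    support = support)
  }
  out
}
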