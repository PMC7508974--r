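#' Enumerate abnormal clusters on a pattern-deviation probability map
#'
#' Finds all maximal connected components of *non-edge* active locations
#' whose PD category is at least as severe as "<5%" (code >= 1). Contiguity
#' is the layout adjacency (8-connectivity by default); blind-spot
#' locations are never members. Components are sorted by size descending,
#' then by their anchor point (most superior, then most nasal).
#'
#' @param pd_cat integer category codes 0..4, one per active location.
#' @param layout a `vf_layout`.
#' @param connectivity 8 (default) or 4.
#' @param hemifield if `TRUE`, clusters may not span the horizontal
#'   midline (default `FALSE`, the permissive reading of "contiguous").
#' @return List of integer vectors of active-location positions (1..52).
#' @export
enumerate_clusters <- function(pd_cat, layout = vf_layout(),
                               connectivity = 8, hemifield = FALSE) {
  if (length(pd_cat) != length(layout$active) || any(is.na(pd_cat))) {
    stop("`pd_cat` must give a category for every active location",
         call. = FALSE)
  }
  a <- layout$locations[layout$active, ]
  eligible <- which(pd_cat >= 1L & !a$edge)
  if (length(eligible) == 0L) return(list())
  adj <- vf_adjacency(layout, connectivity)
  if (hemifield) {
    same_hemi <- outer(sign(a$y), sign(a$y), "==")
    adj <- adj & same_hemi
  }
  # BFS over eligible nodes
  seen <- logical(length(layout$active))
  comps <- list()
  for (s in eligible) {
    if (seen[s]) next
    queue <- s
    seen[s] <- TRUE
    comp <- integer(0)
    while (length(queue)) {
      v <- queue[1]
      queue <- queue[-1]
      comp <- c(comp, v)
      nb <- which(adj[v, ])
      nb <- nb[nb %in% eligible & !seen[nb]]
      seen[nb] <- TRUE
      queue <- c(queue, nb)
    }
    comps[[length(comps) + 1L]] <- sort(comp)
  }
  # sort: size desc, then anchor most superior (max y) then most nasal
  # (min x in the canonical right-eye frame)
  xc <- if (layout$eye == "left") -a$x else a$x
  anchor <- function(comp) {
    ys <- a$y[comp]
    top <- comp[ys == max(ys)]
    top[which.min(xc[top])]
  }
  ord <- order(-lengths(comps),
               -vapply(comps, function(cmp) a$y[anchor(cmp)], numeric(1)),
               vapply(comps, function(cmp) xc[anchor(cmp)], numeric(1)))
  comps[ord]
}

#' Glaucomatous visual-field defect criterion
#'
#' The clinical rule on the pattern-deviation probability plot: a defect is
#' present when some cluster of at least three contiguous non-edge points
#' all depressed at the <5% probability level contains at least one point
#' depressed at the <1% level. "Or worse" always qualifies: a "<0.5%"
#' point satisfies the <1% requirement. All three counted points must be
#' non-edge; edge points neither join nor extend a cluster.
#'
#' @inheritParams enumerate_clusters
#' @return An object of class `vf_defect_call`: list with `is_defect`,
#'   `clusters` (all maximal abnormal components, see
#'   [enumerate_clusters()]) and `qualifying_cluster` (the first cluster
#'   meeting all conditions — largest, ties broken by most severe mean
#'   category — or `integer(0)`).
#' @export
glaucomatous_defect <- function(pd_cat, layout = vf_layout(),
                                connectivity = 8, hemifield = FALSE) {
  comps <- enumerate_clusters(pd_cat, layout, connectivity, hemifield)
  qualifies <- vapply(comps, function(cmp) {
    length(cmp) >= 3L && any(pd_cat[cmp] >= 3L)
  }, logical(1))
  qual <- comps[qualifies]
  if (length(qual) > 1L) {
    ord <- order(-lengths(qual),
                 -vapply(qual, function(cmp) mean(pd_cat[cmp]), numeric(1)))
    qual <- qual[ord]
  }
  structure(
    list(is_defect = length(qual) > 0L,
         clusters = comps,
         qualifying_cluster = if (length(qual)) qual[[1]] else integer(0)),
    class = "vf_defect_call"
  )
}

#' @export
print.vf_defect_call <- function(x, ...) {
  cat(sprintf("Glaucomatous defect: %s (%d abnormal cluster(s))\n",
              if (x$is_defect) "PRESENT" else "absent", length(x$clusters)))
  invisible(x)
}
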