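# Witelson-anchored subregion windows over the 100-node profile.

#' Witelson-anchored region definitions
#'
#' The four streamline windows used for region-level analysis, anchored to the
#' Witelson areal subdivision (0-based node indices, inclusive):
#' Region I = nodes 73-78 (anterior half of the rostral body), Region II =
#' nodes 51-72 (anterior midbody plus the posterior half of the rostral body),
#' Region III = nodes 24-32 (isthmus), Region IV = nodes 13-23 (splenium).
#'
#' @return data.frame: `region`, `start`, `end`, `label`.
#' @export
witelson_regions <- function() {
  data.frame(
    region = c("I", "II", "III", "IV"),
    start = c(73L, 51L, 24L, 13L),
    end = c(78L, 72L, 32L, 23L),
    label = c("rostral body (anterior half)",
              "anterior midbody + rostral body (posterior half)",
              "isthmus", "splenium"),
    stringsAsFactors = FALSE
  )
}

#' Per-subject region mean thickness
#'
#' Arithmetic mean of node thickness within each inclusive node window.
#'
#' @param profiles subjects-by-nodes matrix (100 columns, node 0 first) or a
#'   single `cc_profile`.
#' @param regions region definition data.frame as from [witelson_regions()].
#' @return matrix, subjects by regions.
#' @export
aggregate_regions <- function(profiles, regions = witelson_regions()) {
  if (inherits(profiles, "cc_profile")) profiles <- profile_matrix(profiles)
  profiles <- as.matrix(profiles)
  n_nodes <- ncol(profiles)
  out <- matrix(NA_real_, nrow(profiles), nrow(regions),
                dimnames = list(rownames(profiles), regions$region))
  for (i in seq_len(nrow(regions))) {
    s <- regions$start[i]; e <- regions$end[i]
    if (is.na(s) || is.na(e) || e < s)
      stop_invalid("region %s has an empty node window", regions$region[i])
    if (s < 0L || e > n_nodes - 1L)
      stop_invalid("region %s window [%d, %d] outside nodes 0..%d",
                   regions$region[i], s, e, n_nodes - 1L)
    out[, i] <- rowMeans(profiles[, (s + 1L):(e + 1L), drop = FALSE])
  }
  out
}
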