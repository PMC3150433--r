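# Shared-indel screening: maximal gap runs per taxon per fragment, merged
# across taxa when their bounds coincide exactly, then filtered to
# "high-quality" events -- shared by >= 2 taxa, identical lengths, and no
# staggered ends (no other taxon's gap run partially overlaps the interval).
# Only '-' is a gap; '?' is missing data, never an indel.

#' Detect candidate indel events
#'
#' Every maximal run of `-` per taxon per fragment is a candidate; runs with
#' identical (start, end) across taxa are merged into one event carrying the
#' taxon set. Events never span fragment boundaries. Bounds are 1-based
#' inclusive column indices of the matrix.
#'
#' @param m a [nuc_matrix()]. Fragments are its fragment charsets; a matrix
#'   without fragments is treated as a single fragment spanning all columns.
#' @return data.frame with columns `fragment`, `start`, `end`, `length`,
#'   `n_taxa`, `taxa` (list column).
#' @export
gap_events <- function(m) {
  mat <- as_char_matrix(m)
  frag_cols <- if (length(m$fragments)) {
    m$charsets[m$fragments]
  } else {
    list(all = seq_len(m$n_cols))
  }
  rows <- list()
  for (fr in names(frag_cols)) {
    cols <- frag_cols[[fr]]
    sub <- mat[, cols, drop = FALSE]
    events <- new.env(parent = emptyenv())
    for (i in seq_len(nrow(sub))) {
      r <- rle(sub[i, ] == "-")
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      for (j in which(r$values)) {
        # positions within the fragment must be contiguous matrix columns
        span <- cols[starts[j]:ends[j]]
        segs <- split(span, cumsum(c(1L, diff(span) != 1L)))
        for (seg in segs) {
          key <- paste0(seg[1], ":", seg[length(seg)])
          events[[key]] <- c(events[[key]], m$taxa[i])
        }
      }
    }
    for (key in ls(events)) {
      se <- as.integer(strsplit(key, ":", fixed = TRUE)[[1]])
      rows[[length(rows) + 1L]] <- data.frame(
        fragment = fr, start = se[1], end = se[2],
        length = se[2] - se[1] + 1L,
        n_taxa = length(events[[key]]),
        taxa = I(list(sort(events[[key]]))),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(fragment = character(0), start = integer(0),
                      end = integer(0), length = integer(0),
                      n_taxa = integer(0), taxa = I(list())))
  out <- do.call(rbind, rows)
  out[order(out$fragment, out$start, out$end), , drop = FALSE]
}

#' Filter indel events to high-quality shared deletions
#'
#' Keeps events shared by at least `min_taxa` taxa whose bounds are not
#' straddled by any partially overlapping gap run in another taxon
#' ("no staggered ends, identical lengths"). Flanking sequence identity is
#' not required. The filter is idempotent and its output is a subset of its
#' input.
#'
#' @param events data.frame from [gap_events()]. All events (including
#'   single-taxon runs) should be supplied: the single-taxon runs are what
#'   the staggered-end check tests against.
#' @param min_taxa minimum number of taxa sharing the event (default 2).
#' @return the surviving events with a `quality` column set to `"high"`.
#' @export
quality_filter <- function(events, min_taxa = 2L) {
  if (!nrow(events)) {
    events$quality <- character(0)
    return(events)
  }
  keep <- logical(nrow(events))
  for (i in seq_len(nrow(events))) {
    if (events$n_taxa[i] < min_taxa) next
    same_frag <- events$fragment == events$fragment[i]
    overlap <- same_frag &
      events$start <= events$end[i] & events$end >= events$start[i] &
      !(events$start == events$start[i] & events$end == events$end[i])
    keep[i] <- !any(overlap)
  }
  out <- events[keep, , drop = FALSE]
  if (nrow(out)) out$quality <- "high" else out$quality <- character(0)
  out
}

#' Tabulate indel events for reporting
#'
#' Flattens the taxa list column into a comma-separated string, giving the
#' per-group table layout used for manual audit (fragment, 1-based inclusive
#' bounds, length, taxa, quality).
#'
#' @param events data.frame from [gap_events()] or [quality_filter()].
#' @return data.frame with `taxa` as a character column.
#' @export
indel_report <- function(events) {
  events$taxa <- vapply(events$taxa, paste, character(1), collapse = ",")
  events
}
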