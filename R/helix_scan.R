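#' Enumerate maximal stacked helices in a pair table
#'
#' A helix is a maximal run of consecutively stacked base pairs
#' \code{(i, j), (i+1, j-1), ...} with the two strands disjoint
#' (\code{ik < jk}). Every paired position belongs to exactly one maximal
#' helix; strict stacking is enforced, so a single-nucleotide bulge ends a
#' helix. Works on arbitrary (also pseudoknotted) pair tables.
#'
#' @param pt A \code{pair_table}.
#' @return List of \code{helix} objects in ascending order of the first
#'   5'-strand position. Each has \code{pairs} (k x 2 matrix, i ascending,
#'   j descending), \code{length_bp}, \code{strand5} = \code{[i1, ik]} and
#'   \code{strand3} = \code{[jk, j1]} intervals.
#' @export
enumerate_helices <- function(pt) {
  p <- pt$partner
  n <- pt$n
  helices <- list()
  i <- 1L
  while (i <= n) {
    j <- p[i]
    if (j == 0L || j < i) { i <- i + 1L; next }
    # i opens a pair; extend the stack while (i+m, j-m) is also a pair
    k <- 1L
    while (i + k <= n && j - k > i + k && p[i + k] == j - k) k <- k + 1L
    is <- i:(i + k - 1L)
    js <- j:(j - k + 1L)
    helices[[length(helices) + 1L]] <- new_helix(cbind(is, js))
    i <- i + k
  }
  helices
}

new_helix <- function(pairs) {
  pairs <- matrix(as.integer(pairs), ncol = 2,
                  dimnames = list(NULL, c("i", "j")))
  k <- nrow(pairs)
  stopifnot(k >= 1L, pairs[k, 1] < pairs[k, 2])
  structure(list(pairs = pairs, length_bp = k,
                 strand5 = unname(c(pairs[1, 1], pairs[k, 1])),
                 strand3 = unname(c(pairs[k, 2], pairs[1, 2]))),
            class = "helix")
}

#' @export
print.helix <- function(x, ...) {
  cat(sprintf("<helix> %d bp: [%d,%d] x [%d,%d], strand distance %d nt\n",
              x$length_bp, x$strand5[1], x$strand5[2],
              x$strand3[1], x$strand3[2], strand_distance(x)))
  invisible(x)
}

#' Number of nucleotides between the two helix strands
#'
#' Counts the nucleotides strictly between the innermost base pair
#' (\code{jk - ik - 1}). For a hairpin this is the loop size; the
#' non-hairpin selection requires it to reach the minimum strand distance
#' (default 40 nt).
#'
#' @param h A \code{helix}.
#' @return Integer, nt.
#' @export
strand_distance <- function(h) {
  h$strand3[1] - h$strand5[2] - 1L
}

#' Paired nucleotides inside a helix's linker
#'
#' The linker (inter-segment region) comprises the positions strictly
#' between the innermost pair of the helix. Counted are linker positions
#' with any pairing partner, whether that partner lies inside or outside
#' the linker: the criterion asks for RNA structure where a hairpin would
#' show a loop.
#'
#' @param h A \code{helix}.
#' @param pt The \code{pair_table} the helix came from.
#' @return Integer count of paired linker nucleotides.
#' @export
linker_paired_count <- function(h, pt) {
  lo <- h$strand5[2]; hi <- h$strand3[1]
  if (hi - lo < 2L) return(0L)
  sum(pt$partner[(lo + 1L):(hi - 1L)] > 0L)
}

#' Selection criteria for duplex motifs
#'
#' The defaults encode the non-hairpin duplex definition used throughout
#' the pipeline: at least 8 uninterrupted base pairs, at least 40 nt
#' between the two strands, and at least 16 paired nucleotides in the
#' linker. \code{composition_class} restricts the motif to uniform runs of
#' G:C (or A:U) pairs; \code{hairpin_mode} inverts the distance test
#' (distance strictly below the threshold) to capture classical stems
#' such as GC stem-loops, and does not apply the linker test (a hairpin
#' loop is typically unpaired).
#'
#' @param min_len_bp Minimum duplex length, base pairs (default 8).
#' @param min_strand_distance Minimum nucleotides between strands
#'   (default 40).
#' @param min_linker_paired Minimum paired nucleotides in the linker
#'   (default 16).
#' @param composition_class One of \code{"any"}, \code{"GC"}, \code{"AU"}.
#' @param hairpin_mode Select short-range (stem) rather than long-range
#'   motifs (default FALSE).
#' @return Object of class \code{helix_criteria}.
#' @export
helix_criteria <- function(min_len_bp = 8L, min_strand_distance = 40L,
                           min_linker_paired = 16L,
                           composition_class = c("any", "GC", "AU"),
                           hairpin_mode = FALSE) {
  composition_class <- match.arg(composition_class)
  stopifnot(min_len_bp >= 1L, min_strand_distance >= 0L,
            min_linker_paired >= 0L)
  structure(list(min_len_bp = as.integer(min_len_bp),
                 min_strand_distance = as.integer(min_strand_distance),
                 min_linker_paired = as.integer(min_linker_paired),
                 composition_class = composition_class,
                 hairpin_mode = isTRUE(hairpin_mode)),
            class = "helix_criteria")
}

pair_class <- function(b1, b2) {
  key <- paste0(b1, b2)
  cls <- c(GC = "GC", CG = "GC", AU = "AU", UA = "AU",
           GU = "GU", UG = "GU")[key]
  unname(cls)
}

#' Partition a helix into uniform base-pair composition sub-runs
#'
#' Classifies each pair of the helix as GC (G:C or C:G), AU (A:U or U:A)
#' or GU (the G:U wobble) and splits the helix into maximal consecutive
#' runs of one class. A wobble pair therefore interrupts a GC run: a
#' GC-helix is a run of literally uninterrupted G:C pairs. Non-canonical
#' pairs (e.g. A opposite G) signal a corrupt structure file and are
#' rejected.
#'
#' @param h A \code{helix} with window-local coordinates.
#' @param window_seq The window's RNA sequence.
#' @return List of \code{helix} objects (the sub-runs, in 5' order), each
#'   with an attribute \code{class} in \code{c("GC","AU","GU")}; their
#'   lengths sum to \code{h$length_bp}.
#' @export
composition_subruns <- function(h, window_seq) {
  b <- strsplit(window_seq, "")[[1]]
  if (max(h$pairs) > length(b))
    stop("helix coordinates exceed window sequence length")
  cls <- pair_class(b[h$pairs[, 1]], b[h$pairs[, 2]])
  bad <- which(is.na(cls))
  if (length(bad))
    stop(sprintf("non-complementary pair %s:%s at (%d,%d) - corrupt structure?",
                 b[h$pairs[bad[1], 1]], b[h$pairs[bad[1], 2]],
                 h$pairs[bad[1], 1], h$pairs[bad[1], 2]))
  r <- rle(cls)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  lapply(seq_along(r$values), function(q) {
    sub <- new_helix(h$pairs[starts[q]:ends[q], , drop = FALSE])
    attr(sub, "class_tag") <- r$values[q]
    sub
  })
}

#' Select duplex motifs from one predicted structure
#'
#' Applies the full selection logic to a folded window: maximal helices
#' are enumerated, optionally split into uniform composition sub-runs, and
#' filtered by length, strand distance and linker pairing. With
#' \code{composition_class = "GC"} (or \code{"AU"}) the reported motif is
#' the uniform sub-run, and its distance and linker statistics are
#' computed from the sub-run's own innermost pair, since the sub-run is
#' the motif with its own strand coordinates. In \code{hairpin_mode} the
#' distance test is inverted (strictly below the threshold) and the linker
#' test dropped, yielding stem (hairpin) motifs such as GC-stems.
#'
#' @param structure A \code{structure_record} (window-local coordinates).
#' @param window_seq RNA sequence of the window (required for composition
#'   classes; may be NULL for \code{composition_class = "any"}).
#' @param criteria A \code{helix_criteria}.
#' @return data.frame with one row per selected motif: \code{class},
#'   \code{i1, ik, jk, j1} (window-local strand intervals
#'   strand5 = [i1, ik], strand3 = [jk, j1]), \code{length_bp},
#'   \code{strand_distance}, \code{linker_paired}.
#' @export
select_motifs <- function(structure, window_seq = NULL,
                          criteria = helix_criteria()) {
  stopifnot(inherits(structure, "structure_record"),
            inherits(criteria, "helix_criteria"))
  pt <- structure$pair_table
  helices <- enumerate_helices(pt)
  cand <- list()
  for (h in helices) {
    if (criteria$composition_class == "any") {
      units <- list(h)
      tags <- "general"
    } else {
      if (is.null(window_seq))
        stop("window sequence required for composition-classified scans")
      subs <- composition_subruns(h, window_seq)
      keep <- vapply(subs, function(s)
        attr(s, "class_tag") == criteria$composition_class, logical(1))
      units <- subs[keep]
      tags <- rep(if (criteria$hairpin_mode)
                    paste0(criteria$composition_class, "_stem")
                  else criteria$composition_class,
                  length(units))
    }
    for (q in seq_along(units)) {
      u <- units[[q]]
      if (u$length_bp < criteria$min_len_bp) next
      d <- strand_distance(u)
      if (criteria$hairpin_mode) {
        if (d >= criteria$min_strand_distance) next
        lp <- linker_paired_count(u, pt)
      } else {
        if (d < criteria$min_strand_distance) next
        lp <- linker_paired_count(u, pt)
        if (lp < criteria$min_linker_paired) next
      }
      cand[[length(cand) + 1L]] <- data.frame(
        class = tags[q], i1 = u$strand5[1], ik = u$strand5[2],
        jk = u$strand3[1], j1 = u$strand3[2], length_bp = u$length_bp,
        strand_distance = d, linker_paired = lp,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(cand))
    return(data.frame(class = character(), i1 = integer(), ik = integer(),
                      jk = integer(), j1 = integer(), length_bp = integer(),
                      strand_distance = integer(), linker_paired = integer(),
                      stringsAsFactors = FALSE))
  do.call(rbind, cand)
}
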