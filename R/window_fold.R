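#' Plan sliding folding windows over a transcript
#'
#' Windows of width \code{W} advance by a constant step \code{S}, starting
#' at the 5' end (offset 0). For a transcript longer than the window the
#' number of windows is \code{floor((L - W) / S)}; this convention
#' reproduces the published counts for this pipeline (135 windows for a
#' 3500-nt mRNA and 410 for 9000 nt at W = 800, S = 20), at the cost of
#' possibly leaving up to \code{S - 1} trailing nucleotides uncovered.
#' Set \code{trailing_window = TRUE} to append one extra window ending at
#' position L. A transcript no longer than \code{W} gets exactly one
#' whole-sequence window.
#'
#' @param L Transcript length (nt).
#' @param W Window size, nt (default 800; the pipeline was exercised with
#'   500--1200).
#' @param S Step width, nt (default 20).
#' @param k Structures requested per fold (default 10: the optimal plus
#'   nine suboptimal structures).
#' @param transcript_id Optional id recorded in the plan.
#' @param trailing_window Append a final window ending at L when the
#'   regular grid stops short (default FALSE).
#' @return Object of class \code{window_plan}: \code{offsets} (0-based
#'   window starts), \code{window_size} (per-window width; equals L for the
#'   degenerate single-window case), \code{step}, \code{k},
#'   \code{n_windows}, \code{transcript_id}, \code{L}.
#' @examples
#' enumerate_windows(3500, 800, 20)$n_windows  # 135
#' @export
enumerate_windows <- function(L, W = 800L, S = 20L, k = 10L,
                              transcript_id = NA_character_,
                              trailing_window = FALSE) {
  L <- as.integer(L); W <- as.integer(W); S <- as.integer(S)
  if (is.na(L) || L < 1L) stop("transcript length must be >= 1")
  stopifnot(W >= 1L, S >= 1L, k >= 1L)
  if (L <= W) {
    offsets <- 0L
    W <- L
  } else {
    count <- (L - W) %/% S
    offsets <- S * (seq_len(count) - 1L)
    if (trailing_window && offsets[count] + W < L)
      offsets <- c(offsets, L - W)
  }
  structure(list(transcript_id = transcript_id, window_size = W, step = S,
                 offsets = offsets, k = as.integer(k),
                 n_windows = length(offsets), L = L),
            class = "window_plan")
}

#' @export
print.window_plan <- function(x, ...) {
  cat(sprintf("<window_plan> %s: %d windows of %d nt, step %d, k=%d (L=%d)\n",
              x$transcript_id, x$n_windows, x$window_size, x$step, x$k, x$L))
  invisible(x)
}

#' Construct a folding backend
#'
#' A backend is the pluggable structure-prediction engine behind the
#' pipeline: any object able to return up to k ranked secondary structures
#' for a window sequence satisfies the contract, so essentially any RNA
#' secondary-structure prediction program can drive the scan.
#'
#' @param name Backend name.
#' @param fold Function \code{(seq, k, transcript_id, window_offset)}
#'   returning a list of up to k \code{structure_record}s whose pair
#'   tables have n = nchar(seq).
#' @param has_energies Whether records carry free energies (required by
#'   \code{\link{folding_profile}}).
#' @param stochastic Whether repeated calls may differ.
#' @return Object of class \code{folding_backend}.
#' @export
folding_backend <- function(name, fold, has_energies = TRUE,
                            stochastic = FALSE) {
  stopifnot(is.function(fold))
  structure(list(name = name, fold = fold, has_energies = has_energies,
                 stochastic = stochastic),
            class = "folding_backend")
}

#' @export
print.folding_backend <- function(x, ...) {
  cat(sprintf("<folding_backend> %s (energies: %s)\n", x$name,
              ifelse(x$has_energies, "yes", "no")))
  invisible(x)
}

call_backend <- function(backend, seq, k, transcript_id, offset) {
  recs <- backend$fold(seq, k, transcript_id, offset)
  if (!length(recs)) return(list())
  recs <- recs[seq_len(min(length(recs), k))]
  for (r in seq_along(recs)) {
    if (recs[[r]]$pair_table$n != nchar(seq))
      stop(sprintf("backend '%s' returned a %d-nt structure for a %d-nt window",
                   backend$name, recs[[r]]$pair_table$n, nchar(seq)))
    recs[[r]]$window_offset <- as.integer(offset)
    recs[[r]]$transcript_id <- transcript_id
    recs[[r]]$rank <- r
  }
  recs
}

#' Fold every planned window through a backend
#'
#' Each window sequence is handed to the backend, which returns up to k
#' ranked structures tagged with the window's offset. A failure of one
#' fold is logged (as a warning) and skipped so long batch runs survive
#' sporadic engine errors; a backend returning zero structures for a
#' window simply contributes nothing.
#'
#' @param t An \code{annotated_transcript}.
#' @param plan A \code{window_plan} for \code{t} (default: plan with the
#'   standard 800/20/10 settings).
#' @param backend A \code{folding_backend}.
#' @return List of \code{structure_record}s (at most
#'   \code{plan$n_windows * plan$k}).
#' @export
fold_windows <- function(t, plan = enumerate_windows(t$length,
                                                     transcript_id = t$id),
                         backend) {
  stopifnot(inherits(t, "annotated_transcript"),
            inherits(plan, "window_plan"),
            inherits(backend, "folding_backend"))
  if (any(plan$offsets + plan$window_size > t$length))
    stop("window plan exceeds transcript length")
  out <- list()
  skipped <- integer(0)
  for (off in plan$offsets) {
    seq <- substr(t$sequence, off + 1L, off + plan$window_size)
    recs <- tryCatch(call_backend(backend, seq, plan$k, t$id, off),
                     error = function(e) e)
    if (inherits(recs, "error")) {
      skipped <- c(skipped, off)
      next
    }
    out <- c(out, recs)
  }
  if (length(skipped))
    warning(sprintf("backend '%s' failed on %d/%d windows (offsets: %s)",
                    backend$name, length(skipped), plan$n_windows,
                    paste(utils::head(skipped, 10), collapse = ", ")))
  out
}

#' Local folding-potential profile
#'
#' Slides a short window (default 60 nt, step 1) along the transcript and
#' records the minimum free energy of each window's optimal structure.
#' Local minima of this profile flag stably folded domains. Positions are
#' the 1-based window starts. Suboptimal structures are ignored: only the
#' rank-1 energy enters the profile.
#'
#' @param t An \code{annotated_transcript}.
#' @param backend A \code{folding_backend} that reports energies.
#' @param window Profile window size, nt (default 60).
#' @param step Step width, nt (default 1).
#' @return Object of class \code{folding_profile}: \code{position}
#'   (1-based window starts) and \code{energy} (kcal/mol; 0 for windows
#'   whose best structure has no pairs).
#' @export
folding_profile <- function(t, backend, window = 60L, step = 1L) {
  stopifnot(inherits(t, "annotated_transcript"),
            inherits(backend, "folding_backend"))
  if (!isTRUE(backend$has_energies))
    stop(sprintf("backend '%s' does not report free energies; the folding profile requires them",
                 backend$name))
  if (window > t$length) stop("profile window exceeds transcript length")
  plan <- enumerate_windows(t$length, window, step, k = 1L,
                            transcript_id = t$id)
  energy <- vapply(plan$offsets, function(off) {
    seq <- substr(t$sequence, off + 1L, off + plan$window_size)
    recs <- call_backend(backend, seq, 1L, t$id, off)
    if (!length(recs)) return(NA_real_)
    e <- recs[[1]]$free_energy
    if (is.na(e)) stop(sprintf(
      "backend '%s' returned a structure without energy at offset %d",
      backend$name, off))
    if (sum(recs[[1]]$pair_table$partner > 0) == 0L) 0 else e
  }, numeric(1))
  structure(list(position = plan$offsets + 1L, energy = energy,
                 window = plan$window_size, step = step,
                 transcript_id = t$id),
            class = "folding_profile")
}

#' @export
print.folding_profile <- function(x, ...) {
  cat(sprintf("<folding_profile> %s: %d windows of %d nt; min %.2f kcal/mol at position %d\n",
              x$transcript_id, length(x$position), x$window,
              min(x$energy, na.rm = TRUE),
              x$position[which.min(x$energy)]))
  invisible(x)
}

#' @importFrom graphics points
#' @export
plot.folding_profile <- function(x, ...) {
  plot(x$position, x$energy, type = "l",
       xlab = "window start (nt)", ylab = "MFE (kcal/mol)",
       main = sprintf("Local folding potential: %s (window %d nt)",
                      x$transcript_id, x$window), ...)
  mins <- profile_minima(x)
  if (length(mins))
    points(mins, x$energy[match(mins, x$position)], pch = 19, col = "red")
  invisible(x)
}

#' Local minima of a folding profile
#'
#' A position is a local minimum when its energy is strictly lower than
#' both neighbours; a plateau that is flanked by higher energies on both
#' sides is reported once, at its leftmost position. Profile endpoints are
#' never minima.
#'
#' @param p A \code{folding_profile} (or a list with \code{position} and
#'   \code{energy}).
#' @return Integer vector of 1-based window-start positions.
#' @export
profile_minima <- function(p) {
  e <- p$energy
  if (!length(e)) stop("empty profile")
  if (length(e) < 3L) return(integer(0))
  r <- rle(e)
  starts <- cumsum(c(1L, r$lengths[-length(r$lengths)]))
  mins <- integer(0)
  for (q in seq_along(r$values)) {
    if (q == 1L || q == length(r$values)) next
    if (r$values[q] < r$values[q - 1L] && r$values[q] < r$values[q + 1L])
      mins <- c(mins, starts[q])
  }
  p$position[mins]
}

#' Backend reading precomputed CT files from a directory
#'
#' Expects one CT file per window named
#' \code{<transcript>__<offset>.ct} (possibly holding several concatenated
#' structure records, ranked in file order).
#'
#' @param dir Directory of CT files.
#' @return A \code{folding_backend}.
#' @export
ct_dir_backend <- function(dir) {
  if (!dir.exists(dir)) stop("CT directory not found: ", dir)
  folding_backend(
    name = sprintf("ct-dir(%s)", dir),
    fold = function(seq, k, transcript_id, window_offset) {
      path <- file.path(dir, sprintf("%s__%d.ct", transcript_id,
                                     window_offset))
      if (!file.exists(path)) return(list())
      parse_ct(path, transcript_id, window_offset)
    },
    has_energies = TRUE)
}

#' Backend reading precomputed dot-bracket files from a directory
#'
#' Expects one file per window named \code{<transcript>__<offset>.db}
#' (one structure per line, optional sequence line, optional trailing
#' energy).
#'
#' @param dir Directory of dot-bracket files.
#' @return A \code{folding_backend}.
#' @export
db_dir_backend <- function(dir) {
  if (!dir.exists(dir)) stop("dot-bracket directory not found: ", dir)
  folding_backend(
    name = sprintf("db-dir(%s)", dir),
    fold = function(seq, k, transcript_id, window_offset) {
      path <- file.path(dir, sprintf("%s__%d.db", transcript_id,
                                     window_offset))
      if (!file.exists(path)) return(list())
      parse_dot_bracket_file(path, transcript_id, window_offset)
    },
    has_energies = FALSE)
}

#' Live folding backend via RNAfold
#'
#' Adapter around the ViennaRNA \code{RNAfold} executable (detected on
#' PATH at construction time). Returns the single minimum-free-energy
#' structure per window with its energy; suitable for the folding-potential
#' profile and for k = 1 scans.
#'
#' @param exe Name or path of the RNAfold executable.
#' @return A \code{folding_backend}.
#' @export
rnafold_backend <- function(exe = "RNAfold") {
  path <- Sys.which(exe)
  if (!nzchar(path))
    stop("folding engine not available: '", exe, "' not found on PATH")
  folding_backend(
    name = sprintf("engine(%s)", exe),
    fold = function(seq, k, transcript_id, window_offset) {
      out <- system2(path, c("--noPS"), input = seq, stdout = TRUE)
      if (length(out) < 2L) stop("RNAfold produced no structure")
      line <- out[2]
      db <- sub("\\s.*$", "", line)
      em <- regmatches(line, regexpr("-?[0-9]+\\.?[0-9]*(?=\\s*\\)\\s*$)",
                                     line, perl = TRUE))
      energy <- if (length(em)) as.numeric(em) else NA_real_
      list(structure_record(parse_dot_bracket(db), free_energy = energy))
    },
    has_energies = TRUE)
}
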