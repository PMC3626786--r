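# Run code with a locally seeded RNG, restoring the caller's stream.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

rev_comp_rna <- function(s) {
  chartr("ACGU", "UGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

#' Shuffle a transcript within its annotation regions
#'
#' Permutes the nucleotides independently within the 5'-UTR, the CDS and
#' the 3'-UTR (the annotation regions, deliberately distinct from the
#' analysis 5'-region/rCDS partition), conserving each region's
#' mononucleotide counts exactly. Seeded, hence reproducible; the caller's
#' RNG stream is left untouched.
#'
#' @param t An \code{annotated_transcript}.
#' @param seed Integer seed.
#' @param suffix Appended to the transcript id (default \code{"_shuf"}).
#' @return A shuffled \code{annotated_transcript} with the same
#'   annotation.
#' @export
shuffle_regions <- function(t, seed, suffix = "_shuf") {
  stopifnot(inherits(t, "annotated_transcript"))
  b <- strsplit(t$sequence, "")[[1]]
  bounds <- list(c(1L, t$utr5_len), c(t$utr5_len + 1L, t$cds_end),
                 c(t$cds_end + 1L, t$length))
  with_seed(seed, {
    for (iv in bounds) {
      if (iv[2] < iv[1]) next
      idx <- iv[1]:iv[2]
      b[idx] <- b[sample(idx)]
    }
  })
  annotated_transcript(paste0(t$id, suffix), paste(b, collapse = ""),
                       t$utr5_len, t$cds_end, t$metadata)
}

#' Build a pool of region-shuffled control transcripts
#'
#' Generates \code{n_replicates} independent shuffles of every transcript.
#' Per-replicate seeds are derived from the master seed by mixing in the
#' transcript and replicate indices
#' (\code{(seed + 1000003*rep + 7919*transcript) mod (2^31 - 1)}), so the
#' whole pool is reproducible from one integer.
#'
#' @param pool List of \code{annotated_transcript}s.
#' @param n_replicates Shuffles per transcript (>= 1).
#' @param seed Master seed.
#' @return List of shuffled transcripts, ids suffixed
#'   \code{_shuf<replicate>}.
#' @export
build_shuffled_pool <- function(pool, n_replicates, seed) {
  stopifnot(n_replicates >= 1L)
  if (inherits(pool, "annotated_transcript")) pool <- list(pool)
  out <- list()
  for (r in seq_len(n_replicates)) {
    for (ti in seq_along(pool)) {
      sub <- (as.numeric(seed) + 1000003 * r + 7919 * ti) %% 2147483647
      out[[length(out) + 1L]] <- shuffle_regions(
        pool[[ti]], as.integer(sub), suffix = sprintf("_shuf%d", r))
    }
  }
  out
}

#' Generate a synthetic transcript with a planted long-range duplex
#'
#' Builds a background of low self-complementarity (A/C only, so no
#' canonical pairs can form within it), plants two exactly
#' reverse-complementary strands of the requested length and class at the
#' requested strand distance, and plants a small G:C hairpin (plus, for
#' odd counts, one crossing pair reaching outside the duplex) inside the
#' linker so that exactly \code{linker_paired} linker nucleotides are
#' paired. Returns the transcript together with a truth record describing
#' every planted pair.
#'
#' @param length_bp Duplex length, bp.
#' @param strand_distance Nucleotides between the innermost pair.
#' @param linker_paired Paired nucleotides to plant inside the linker.
#' @param class \code{"GC"}, \code{"AU"} or \code{"mixed"}.
#' @param background_length Total transcript length, nt.
#' @param seed Integer seed.
#' @param duplex_start 1-based start of the 5' strand (default: centred).
#' @param utr5_len,cds_end Annotation (defaults: 10\% / 90\% of length).
#' @param id Transcript id.
#' @return List with \code{transcript} (an \code{annotated_transcript})
#'   and \code{truth} (class \code{planted_truth}: strand intervals, the
#'   full planted pair list, class, and the generation parameters).
#' @export
plant_duplex_sequence <- function(length_bp, strand_distance, linker_paired,
                                  class = c("GC", "AU", "mixed"),
                                  background_length = 1000L, seed = 1L,
                                  duplex_start = NULL, utr5_len = NULL,
                                  cds_end = NULL, id = NULL) {
  class <- match.arg(class)
  k <- as.integer(length_bp); d <- as.integer(strand_distance)
  lp <- as.integer(linker_paired); L <- as.integer(background_length)
  stopifnot(k >= 1L, d >= 0L, lp >= 0L, L >= 1L)
  h <- lp %/% 2L
  cross <- lp %% 2L == 1L
  span <- 2L * k + d
  if (is.null(duplex_start)) duplex_start <- max(1L, (L - span) %/% 2L)
  s <- as.integer(duplex_start)
  j1 <- s + span - 1L
  if (s < 1L || j1 > L)
    stop("infeasible geometry: duplex does not fit in the background")
  if (h > 0L && 2L * h + 4L > d)
    stop("infeasible geometry: linker too short for the requested paired nucleotides")
  if (cross && j1 + 2L > L)
    stop("infeasible geometry: no room for the crossing pair target")
  if (is.null(id))
    id <- sprintf("planted_%s_%dbp_d%d_lp%d", class, k, d, lp)
  alphabet <- switch(class, GC = c("G", "C"), AU = c("A", "U"),
                     mixed = c("A", "C", "G", "U"))
  b <- with_seed(seed, {
    bg <- sample(c("A", "C"), L, replace = TRUE)
    s5 <- sample(alphabet, k, replace = TRUE)
    stem <- if (h > 0L) sample(c("G", "C"), h, replace = TRUE) else character(0)
    list(bg = bg, s5 = s5, stem = stem)
  })
  seqv <- b$bg
  seqv[s:(s + k - 1L)] <- b$s5
  s3 <- strsplit(rev_comp_rna(paste(b$s5, collapse = "")), "")[[1]]
  s3_start <- s + k + d
  seqv[s3_start:j1] <- s3
  pairs <- cbind(s:(s + k - 1L), j1:(s3_start))
  if (h > 0L) {
    hp_span <- 2L * h + 4L
    ls <- s + k + (d - hp_span) %/% 2L
    stem2 <- strsplit(rev_comp_rna(paste(b$stem, collapse = "")), "")[[1]]
    seqv[ls:(ls + h - 1L)] <- b$stem
    seqv[(ls + h):(ls + h + 3L)] <- "A"
    seqv[(ls + h + 4L):(ls + hp_span - 1L)] <- stem2
    pairs <- rbind(pairs, cbind(ls:(ls + h - 1L),
                                (ls + hp_span - 1L):(ls + h + 4L)))
  }
  if (cross) {
    p <- s + k + d - 1L            # last linker position
    q <- j1 + 2L                   # outside the duplex
    seqv[p] <- "G"; seqv[q] <- "C"
    pairs <- rbind(pairs, c(p, q))
  }
  if (is.null(utr5_len)) utr5_len <- L %/% 10L
  if (is.null(cds_end)) cds_end <- (L * 9L) %/% 10L
  tr <- annotated_transcript(id, paste(seqv, collapse = ""),
                             utr5_len, cds_end)
  truth <- structure(list(
    transcript_id = id,
    strand5 = c(s, s + k - 1L), strand3 = c(s3_start, j1),
    pairs = pairs, class = class,
    params = list(length_bp = k, strand_distance = d,
                  linker_paired = lp, background_length = L, seed = seed)),
    class = "planted_truth")
  list(transcript = tr, truth = truth)
}

#' Deterministic folding backend built from planted truths
#'
#' For every window the backend returns exactly one structure pairing
#' precisely those truth pairs that lie fully inside the window (in
#' window-local coordinates) and nothing else, with an energy of
#' -2 kcal/mol per pair. When \code{sequences} is supplied (a named
#' character vector or list of transcript sequences), truth pairs whose
#' bases are no longer canonical/wobble complementary in that sequence
#' are dropped -- this is how shuffled controls are scanned: shuffling
#' destroys the planted complementarity and the backend no longer pairs
#' the broken positions. Unknown transcripts yield an all-unpaired
#' structure.
#'
#' @param truths A \code{planted_truth} or list of them (several per
#'   transcript are merged).
#' @param sequences Optional named sequences for complementarity checking.
#' @return A deterministic \code{folding_backend}.
#' @export
planted_backend <- function(truths, sequences = NULL) {
  if (inherits(truths, "planted_truth")) truths <- list(truths)
  by_id <- split(truths, vapply(truths, `[[`, "", "transcript_id"))
  pair_map <- lapply(by_id, function(ts)
    do.call(rbind, lapply(ts, `[[`, "pairs")))
  if (!is.null(sequences) && is.list(sequences))
    sequences <- unlist(sequences)
  canonical <- c("GC", "CG", "AU", "UA", "GU", "UG")
  folding_backend(
    name = "fixture(planted)",
    fold = function(seq, k, transcript_id, window_offset) {
      n <- nchar(seq)
      partner <- integer(n)
      pm <- pair_map[[transcript_id]]
      if (!is.null(pm)) {
        lo <- window_offset + 1L; hi <- window_offset + n
        inside <- pm[, 1] >= lo & pm[, 1] <= hi &
                  pm[, 2] >= lo & pm[, 2] <= hi
        pm <- pm[inside, , drop = FALSE]
        if (!is.null(sequences) && nrow(pm)) {
          sq <- sequences[[transcript_id]]
          ok <- paste0(substring(sq, pm[, 1], pm[, 1]),
                       substring(sq, pm[, 2], pm[, 2])) %in% canonical
          pm <- pm[ok, , drop = FALSE]
        }
        if (nrow(pm)) {
          partner[pm[, 1] - window_offset] <- pm[, 2] - window_offset
          partner[pm[, 2] - window_offset] <- pm[, 1] - window_offset
        }
      }
      list(structure_record(pair_table(partner),
                            free_energy = -2 * (sum(partner > 0L) / 2)))
    },
    has_energies = TRUE)
}

#' Write a complete synthetic fixture to disk
#'
#' Emits FASTA, annotation TSV, a truth JSON and a CT-directory rendering
#' of the planted structures (one CT file per planned window, named
#' \code{<transcript>__<offset>.ct}), so the precomputed-CT reading path
#' can be exercised end to end without a folding engine.
#'
#' @param planted List of \code{plant_duplex_sequence} results (or one).
#' @param dir Output directory (created if needed).
#' @param window,step Window plan used for the CT rendering.
#' @return Invisibly, a named vector of the paths written.
#' @export
make_fixture <- function(planted, dir, window = 800L, step = 20L) {
  if (!is.null(planted$transcript)) planted <- list(planted)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ct_dir <- file.path(dir, "ct")
  dir.create(ct_dir, showWarnings = FALSE)
  transcripts <- lapply(planted, `[[`, "transcript")
  truths <- lapply(planted, `[[`, "truth")
  fasta <- file.path(dir, "transcripts.fa")
  ann <- file.path(dir, "annotation.tsv")
  write_transcripts(transcripts, fasta, ann)
  truth_json <- file.path(dir, "truth.json")
  jsonlite::write_json(lapply(truths, function(tr) {
    list(transcript_id = tr$transcript_id, strand5 = tr$strand5,
         strand3 = tr$strand3, class = tr$class,
         pairs = unname(apply(tr$pairs, 1, as.list)), params = tr$params)
  }), truth_json, auto_unbox = TRUE)
  backend <- planted_backend(truths)
  for (t in transcripts) {
    plan <- enumerate_windows(t$length, window, step, k = 1L,
                              transcript_id = t$id)
    for (off in plan$offsets) {
      wseq <- substr(t$sequence, off + 1L, off + plan$window_size)
      rec <- backend$fold(wseq, 1L, t$id, off)[[1]]
      write_ct(rec, wseq,
               file.path(ct_dir, sprintf("%s__%d.ct", t$id, off)))
    }
  }
  invisible(c(fasta = fasta, annotation = ann, truth = truth_json,
              ct_dir = ct_dir))
}
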