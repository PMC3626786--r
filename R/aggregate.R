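#' Map window-local motif coordinates to transcript coordinates
#'
#' Shifts every coordinate column of a window-local motif table by the
#' window's 0-based offset. Reversible (\code{map_to_global(x, -offset)}
#' undoes it).
#'
#' @param motifs Motif data.frame from \code{\link{select_motifs}}.
#' @param window_offset 0-based offset of the window within the transcript.
#' @param transcript_length Optional length for a bounds check.
#' @return The motif table in global 1-based coordinates.
#' @export
map_to_global <- function(motifs, window_offset, transcript_length = NULL) {
  off <- as.integer(window_offset)
  for (col in c("i1", "ik", "jk", "j1")) motifs[[col]] <- motifs[[col]] + off
  if (!is.null(transcript_length) && nrow(motifs) &&
      (any(motifs$j1 > transcript_length) || any(motifs$i1 < 1L)))
    stop("mapped motif exceeds transcript bounds - inconsistent record")
  motifs
}

#' Deduplicate motifs across windows and suboptimal structures
#'
#' The same physical duplex is predicted again and again as the window
#' slides and as suboptimal structures repeat it; its identity is the
#' exact key (class, strand5 interval, strand3 interval) in transcript
#' coordinates. Each key becomes one record whose \code{support} is the
#' number of distinct structures containing it and whose
#' \code{eligible} is the number of structures whose window spans both
#' strands (so the support fraction is comparable across positions).
#'
#' @param candidates data.frame of global-coordinate motifs carrying
#'   \code{structure_key} and the selection columns (as produced inside
#'   \code{\link{scan_transcript}}).
#' @param structures The list of \code{structure_record}s that was
#'   scanned (used to count eligible structures per key).
#' @return data.frame with one row per motif key: coordinates, class,
#'   length/distance/linker statistics, \code{support}, \code{eligible},
#'   \code{support_fraction}.
#' @export
deduplicate_motifs <- function(candidates, structures) {
  if (!nrow(candidates)) {
    return(data.frame(class = character(), i1 = integer(), ik = integer(),
                      jk = integer(), j1 = integer(), length_bp = integer(),
                      strand_distance = integer(), linker_paired = integer(),
                      support = integer(), eligible = integer(),
                      support_fraction = numeric(), stringsAsFactors = FALSE))
  }
  key <- paste(candidates$class, candidates$i1, candidates$ik,
               candidates$jk, candidates$j1, sep = "|")
  # windows of each structure, for eligibility
  w_start <- vapply(structures, function(s) s$window_offset + 1L, integer(1))
  w_end <- vapply(structures, function(s) s$window_offset + s$pair_table$n,
                  integer(1))
  rows <- lapply(split(seq_len(nrow(candidates)), key), function(idx) {
    r <- candidates[idx[1], ]
    support <- length(unique(candidates$structure_key[idx]))
    eligible <- sum(w_start <= r$i1 & w_end >= r$j1)
    data.frame(class = r$class, i1 = r$i1, ik = r$ik, jk = r$jk, j1 = r$j1,
               length_bp = r$length_bp, strand_distance = r$strand_distance,
               linker_paired = r$linker_paired, support = support,
               eligible = eligible,
               support_fraction = support / eligible,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$i1, out$jk, out$class), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Region label of a motif
#'
#' A motif is assigned the region of the 5'-most nucleotide of its 5'
#' strand; a motif straddling a region boundary therefore carries a single
#' label, which keeps per-region counts summing to the transcript total.
#'
#' @param m Motif data.frame with column \code{i1} (global coordinates).
#' @param scheme A \code{region_scheme}.
#' @return Character vector of region labels.
#' @export
assign_motif_region <- function(m, scheme) {
  if (!nrow(m)) return(character(0))
  assign_region(m$i1, scheme)
}

#' Distance of a motif from the start codon
#'
#' Nucleotides from the 5' strand's first position to the first CDS
#' nucleotide: negative upstream of the AUG, 0 at the A of the AUG.
#'
#' @param m Motif data.frame with column \code{i1}.
#' @param utr5_len 5'-UTR length of the transcript.
#' @return Integer vector, nt.
#' @export
distance_from_start_codon <- function(m, utr5_len) {
  as.integer(m$i1 - (utr5_len + 1L))
}

#' Scan one transcript for duplex motifs
#'
#' Runs the full per-transcript pipeline: plan windows, fold each through
#' the backend, scan every predicted structure, map candidates to
#' transcript coordinates, deduplicate, and annotate with region and
#' distance from the start codon.
#'
#' @param t An \code{annotated_transcript}.
#' @param backend A \code{folding_backend}.
#' @param criteria A \code{helix_criteria}.
#' @param window,step,structures Window size, step width and structures
#'   per fold (defaults 800 / 20 / 10).
#' @param plan Optional precomputed \code{window_plan} (overrides
#'   \code{window}/\code{step}/\code{structures}).
#' @return data.frame of \code{MotifRecord} rows: \code{transcript_id},
#'   \code{class}, strand intervals with sequences, \code{length_bp},
#'   \code{strand_distance}, \code{linker_paired}, \code{support},
#'   \code{eligible}, \code{support_fraction}, \code{region},
#'   \code{distance_from_start}.
#' @export
scan_transcript <- function(t, backend, criteria = helix_criteria(),
                            window = 800L, step = 20L, structures = 10L,
                            plan = NULL) {
  if (is.null(plan))
    plan <- enumerate_windows(t$length, window, step, structures,
                              transcript_id = t$id)
  recs <- fold_windows(t, plan, backend)
  cand <- lapply(seq_along(recs), function(s) {
    rec <- recs[[s]]
    wseq <- substr(t$sequence, rec$window_offset + 1L,
                   rec$window_offset + rec$pair_table$n)
    m <- select_motifs(rec, wseq, criteria)
    if (!nrow(m)) return(NULL)
    m <- map_to_global(m, rec$window_offset, t$length)
    m$structure_key <- s
    m
  })
  cand <- do.call(rbind, cand)
  if (is.null(cand))
    cand <- data.frame(class = character(), i1 = integer(), ik = integer(),
                       jk = integer(), j1 = integer(), length_bp = integer(),
                       strand_distance = integer(),
                       linker_paired = integer(), structure_key = integer(),
                       stringsAsFactors = FALSE)
  dedup <- deduplicate_motifs(cand, recs)
  scheme <- define_regions(t)
  n <- nrow(dedup)
  if (n == 0L)
    return(data.frame(
      transcript_id = character(), class = character(),
      strand5_seq = character(), strand5_start = integer(),
      strand5_end = integer(), strand3_seq = character(),
      strand3_start = integer(), strand3_end = integer(),
      length_bp = integer(), strand_distance = integer(),
      linker_paired = integer(), support = integer(),
      eligible = integer(), support_fraction = numeric(),
      region = character(), distance_from_start = integer(),
      stringsAsFactors = FALSE))
  data.frame(
    transcript_id = rep(t$id, n),
    class = dedup$class,
    strand5_seq = substring(t$sequence, dedup$i1, dedup$ik),
    strand5_start = dedup$i1, strand5_end = dedup$ik,
    strand3_seq = substring(t$sequence, dedup$jk, dedup$j1),
    strand3_start = dedup$jk, strand3_end = dedup$j1,
    length_bp = dedup$length_bp,
    strand_distance = dedup$strand_distance,
    linker_paired = dedup$linker_paired,
    support = dedup$support, eligible = dedup$eligible,
    support_fraction = dedup$support_fraction,
    region = assign_motif_region(dedup, scheme),
    distance_from_start = distance_from_start_codon(dedup, t$utr5_len),
    stringsAsFactors = FALSE)
}

#' Scan a pool of transcripts
#'
#' Applies \code{\link{scan_transcript}} to every transcript and collects
#' motifs, per-region frequencies and per-class summary statistics into a
#' single result object.
#'
#' @inheritParams scan_transcript
#' @param transcripts List of \code{annotated_transcript}s.
#' @return Object of class \code{duplex_scan}: \code{motifs} (motif
#'   table), \code{frequencies} (per-100-nt region table),
#'   \code{stats} (per-class distance/length summaries),
#'   \code{presence} (per-transcript motif presence), \code{log}
#'   (counts per stage), plus the scan settings.
#' @export
scan_transcripts <- function(transcripts, backend,
                             criteria = helix_criteria(),
                             window = 800L, step = 20L, structures = 10L) {
  if (inherits(transcripts, "annotated_transcript"))
    transcripts <- list(transcripts)
  motifs <- do.call(rbind, lapply(transcripts, scan_transcript,
                                  backend = backend, criteria = criteria,
                                  window = window, step = step,
                                  structures = structures))
  n_windows <- sum(vapply(transcripts, function(t)
    enumerate_windows(t$length, window, step)$n_windows, integer(1)))
  freqs <- frequency_per_100nt(motifs, transcripts)
  present <- vapply(transcripts, function(t)
    sum(motifs$transcript_id == t$id) > 0L, logical(1))
  structure(list(
    motifs = motifs, frequencies = freqs,
    stats = strand_distance_stats(motifs),
    presence = data.frame(
      transcript_id = vapply(transcripts, `[[`, "", "id"),
      n_motifs = vapply(transcripts, function(t)
        sum(motifs$transcript_id == t$id), integer(1)),
      has_motif = present, row.names = NULL),
    log = c(transcripts = length(transcripts), windows = n_windows,
            motifs = nrow(motifs)),
    criteria = criteria, window = window, step = step,
    structures = structures),
    class = "duplex_scan")
}

#' @export
print.duplex_scan <- function(x, ...) {
  cat(sprintf("<duplex_scan> %d transcript(s), %d windows planned, %d motif(s) [%s]\n",
              x$log[["transcripts"]], x$log[["windows"]],
              x$log[["motifs"]],
              paste(unique(x$motifs$class), collapse = ", ")))
  cat(sprintf("  criteria: >=%d bp, strand distance %s%d nt, linker >=%d paired nt, class %s\n",
              x$criteria$min_len_bp,
              ifelse(x$criteria$hairpin_mode, "<", ">="),
              x$criteria$min_strand_distance,
              x$criteria$min_linker_paired, x$criteria$composition_class))
  invisible(x)
}

#' @export
summary.duplex_scan <- function(object, ...) {
  cat(sprintf("Scan of %d transcript(s): %d motif(s); %d/%d transcript(s) with >=1 motif\n",
              object$log[["transcripts"]], object$log[["motifs"]],
              sum(object$presence$has_motif), nrow(object$presence)))
  pooled <- object$frequencies[object$frequencies$transcript_id == "(pooled)", ]
  if (nrow(pooled)) {
    cat("Pooled frequencies per 100 nt:\n")
    print(pooled[, c("region", "region_length", "class", "count",
                     "freq_per_100nt")], row.names = FALSE)
  }
  if (nrow(object$stats)) {
    cat("Per-class strand distance and length (mean +/- SD):\n")
    print(object$stats, row.names = FALSE)
  }
  invisible(object)
}

#' Per-region motif frequencies per 100 nt
#'
#' For every transcript and every class present, counts motifs per
#' analysis region and normalizes by region length:
#' \code{freq = 100 * count / region_length}. A \code{whole} row uses the
#' full transcript length. Pooled rows (transcript_id \code{"(pooled)"})
#' aggregate the whole set: pooled frequency = 100 * total count / total
#' region length. Empty regions are omitted (frequency undefined).
#'
#' @param motifs Motif table (as from \code{\link{scan_transcript}}).
#' @param transcripts The list of scanned \code{annotated_transcript}s.
#' @return data.frame with columns \code{transcript_id}, \code{region},
#'   \code{region_length}, \code{class}, \code{count},
#'   \code{freq_per_100nt}.
#' @export
frequency_per_100nt <- function(motifs, transcripts) {
  if (inherits(transcripts, "annotated_transcript"))
    transcripts <- list(transcripts)
  classes <- sort(unique(motifs$class))
  if (!length(classes)) classes <- "general"
  regions <- c("five_prime", "rcds", "utr3", "whole")
  rows <- list()
  for (t in transcripts) {
    scheme <- define_regions(t)
    rlen <- c(scheme$lengths, whole = t$length)
    mt <- motifs[motifs$transcript_id == t$id, , drop = FALSE]
    for (cl in classes) {
      mc <- mt[mt$class == cl, , drop = FALSE]
      for (r in regions) {
        L <- rlen[[r]]
        if (L == 0L) next
        cnt <- if (r == "whole") nrow(mc) else sum(mc$region == r)
        rows[[length(rows) + 1L]] <- data.frame(
          transcript_id = t$id, region = r, region_length = L,
          class = cl, count = cnt, freq_per_100nt = 100 * cnt / L,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  # pooled rows over the whole set
  pooled <- lapply(classes, function(cl) {
    oc <- out[out$class == cl, , drop = FALSE]
    do.call(rbind, lapply(regions, function(r) {
      or <- oc[oc$region == r, , drop = FALSE]
      if (!nrow(or)) return(NULL)
      data.frame(transcript_id = "(pooled)", region = r,
                 region_length = sum(or$region_length), class = cl,
                 count = sum(or$count),
                 freq_per_100nt = 100 * sum(or$count) / sum(or$region_length),
                 stringsAsFactors = FALSE)
    }))
  })
  out <- rbind(out, do.call(rbind, pooled))
  rownames(out) <- NULL
  out
}

#' Mean and standard deviation of strand distance and duplex length
#'
#' Per motif class: arithmetic mean and sample (n-1) standard deviation of
#' the strand distance and of the duplex length in bp. Groups of size 1
#' report SD 0 and are flagged in the \code{single} column; empty groups
#' are simply absent.
#'
#' @param motifs Motif table with columns \code{class},
#'   \code{strand_distance}, \code{length_bp}.
#' @return data.frame with one row per class: \code{n},
#'   \code{mean_distance}, \code{sd_distance}, \code{mean_length_bp},
#'   \code{sd_length_bp}, \code{single}.
#' @export
strand_distance_stats <- function(motifs) {
  if (!nrow(motifs))
    return(data.frame(class = character(), n = integer(),
                      mean_distance = numeric(), sd_distance = numeric(),
                      mean_length_bp = numeric(), sd_length_bp = numeric(),
                      single = logical(), stringsAsFactors = FALSE))
  sd0 <- function(x) if (length(x) < 2L) 0 else stats::sd(x)
  rows <- lapply(split(motifs, motifs$class), function(g) {
    data.frame(class = g$class[1], n = nrow(g),
               mean_distance = mean(g$strand_distance),
               sd_distance = sd0(g$strand_distance),
               mean_length_bp = mean(g$length_bp),
               sd_length_bp = sd0(g$length_bp),
               single = nrow(g) == 1L, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$class), , drop = FALSE]
  rownames(out) <- NULL
  out
}

motif_table_columns <- c(
  "transcript_id", "class", "strand5_seq", "strand5_start", "strand5_end",
  "strand3_seq", "strand3_start", "strand3_end", "length_bp",
  "strand_distance", "linker_paired", "support", "eligible",
  "support_fraction", "region", "distance_from_start")

#' Write the motif table as TSV
#'
#' Fixed header and a deterministic row order (transcript, 5'-strand
#' start, class): re-running on identical input yields a byte-identical
#' file.
#'
#' @param motifs Motif table (as from \code{\link{scan_transcript}}).
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_motif_table <- function(motifs, path) {
  m <- motifs[order(motifs$transcript_id, motifs$strand5_start,
                    motifs$class), motif_table_columns, drop = FALSE]
  utils::write.table(m, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write the per-region frequency table as TSV
#'
#' @param freqs Frequency table from \code{\link{frequency_per_100nt}}.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_region_table <- function(freqs, path) {
  f <- freqs[order(freqs$transcript_id != "(pooled)", freqs$transcript_id,
                   match(freqs$region, c("five_prime", "rcds", "utr3",
                                         "whole")), freqs$class), ,
             drop = FALSE]
  utils::write.table(f, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
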