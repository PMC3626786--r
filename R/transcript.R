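#' Normalize a nucleotide sequence to the RNA alphabet
#'
#' Upper-cases the input and replaces T by U. Any character outside
#' \code{A,C,G,T,U} (either case) is rejected with the 1-based position of
#' the first offending symbol. Ambiguity codes such as \code{N} are refused
#' rather than randomized: the scan requires fully determined sequences.
#'
#' @param raw Character scalar, DNA or RNA sequence.
#' @return Character scalar over \code{A,C,G,U}, same length as input.
#' @examples
#' normalize_sequence("acgt")  # "ACGU"
#' @export
normalize_sequence <- function(raw) {
  stopifnot(is.character(raw), length(raw) == 1L)
  if (nchar(raw) == 0L) stop("empty sequence")
  up <- chartr("acgtu", "ACGTU", raw)
  up <- chartr("T", "U", up)
  bad <- regexpr("[^ACGU]", up)
  if (bad > 0L) {
    stop(sprintf("invalid character '%s' at position %d",
                 substr(raw, bad, bad), bad))
  }
  up
}

#' Construct an annotated transcript
#'
#' Bundles an mRNA sequence with its functional annotation: the length of
#' the 5'-UTR and the 1-based position of the last CDS nucleotide. The
#' sequence is normalized to the RNA alphabet (T to U, upper case).
#' Coordinates are 1-based and intervals closed throughout the package.
#'
#' @param id Transcript identifier.
#' @param sequence Nucleotide sequence (DNA or RNA alphabet).
#' @param utr5_len Number of 5'-UTR nucleotides (>= 0).
#' @param cds_end 1-based position of the last CDS nucleotide.
#' @param metadata Optional named list (organism, gene family, ...).
#' @return Object of class \code{annotated_transcript} with elements
#'   \code{id}, \code{sequence}, \code{length}, \code{utr5_len},
#'   \code{cds_end}, \code{metadata}.
#' @export
annotated_transcript <- function(id, sequence, utr5_len, cds_end,
                                 metadata = list()) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  sequence <- normalize_sequence(sequence)
  n <- nchar(sequence)
  utr5_len <- as.integer(utr5_len)
  cds_end <- as.integer(cds_end)
  if (is.na(utr5_len) || utr5_len < 0L)
    stop("utr5_len must be a non-negative integer")
  if (is.na(cds_end) || utr5_len >= cds_end || cds_end > n)
    stop(sprintf(
      "annotation must satisfy 0 <= utr5_len < cds_end <= length: got utr5_len=%d, cds_end=%d, length=%d",
      utr5_len, cds_end, n))
  structure(
    list(id = id, sequence = sequence, length = n,
         utr5_len = utr5_len, cds_end = cds_end, metadata = metadata),
    class = "annotated_transcript")
}

#' @export
print.annotated_transcript <- function(x, ...) {
  cat(sprintf("<annotated_transcript> %s: %d nt (5'-UTR %d nt, CDS ends %d, 3'-UTR %d nt)\n",
              x$id, x$length, x$utr5_len, x$cds_end, x$length - x$cds_end))
  invisible(x)
}

#' Partition a transcript into its three analysis regions
#'
#' The analysis partition is distinct from the annotation: the 5'-region
#' comprises the 5'-UTR plus the first 200 nt of coding sequence, the rCDS
#' is the coding sequence remaining after those 200 nt, and the 3'-UTR is
#' everything downstream of the CDS. When the CDS is shorter than 200 nt
#' the 5'-region is capped at \code{cds_end} so the three closed intervals
#' always partition \code{[1, length]} without overlap or gap (empty
#' intervals are permitted and reported with length 0).
#'
#' @param t An \code{annotated_transcript}.
#' @param cds_lead Number of coding nucleotides absorbed into the
#'   5'-region (default 200).
#' @return Object of class \code{region_scheme}: a list with
#'   \code{five_prime}, \code{rcds}, \code{utr3} (each
#'   \code{c(start, end)}, or \code{NULL} if empty), per-region
#'   \code{lengths}, and the transcript \code{length}.
#' @export
define_regions <- function(t, cds_lead = 200L) {
  stopifnot(inherits(t, "annotated_transcript"))
  fp_end <- min(t$utr5_len + as.integer(cds_lead), t$cds_end)
  iv <- function(a, b) if (b >= a) c(a, b) else NULL
  five_prime <- iv(1L, fp_end)
  rcds <- iv(fp_end + 1L, t$cds_end)
  utr3 <- iv(t$cds_end + 1L, t$length)
  len <- function(x) if (is.null(x)) 0L else x[2] - x[1] + 1L
  structure(
    list(five_prime = five_prime, rcds = rcds, utr3 = utr3,
         lengths = c(five_prime = len(five_prime), rcds = len(rcds),
                     utr3 = len(utr3)),
         length = t$length),
    class = "region_scheme")
}

#' Region label of a single position
#'
#' @param pos 1-based position (vectorized).
#' @param scheme A \code{region_scheme} from \code{\link{define_regions}}.
#' @return Character vector of labels among
#'   \code{"five_prime"}, \code{"rcds"}, \code{"utr3"}.
#' @export
assign_region <- function(pos, scheme) {
  stopifnot(inherits(scheme, "region_scheme"))
  pos <- as.integer(pos)
  if (any(is.na(pos)) || any(pos < 1L) || any(pos > scheme$length))
    stop(sprintf("position out of range 1..%d", scheme$length))
  out <- character(length(pos))
  for (r in c("five_prime", "rcds", "utr3")) {
    iv <- scheme[[r]]
    if (!is.null(iv)) out[pos >= iv[1] & pos <= iv[2]] <- r
  }
  out
}

#' Per-region nucleotide composition
#'
#' Fractions of A, C, G, U within each analysis region. For a non-empty
#' region the four fractions sum to 1; empty regions are reported with
#' \code{NA} fractions and length 0.
#'
#' @param t An \code{annotated_transcript}.
#' @param scheme Optional precomputed \code{region_scheme}.
#' @return data.frame with columns \code{region}, \code{length},
#'   \code{A}, \code{C}, \code{G}, \code{U}.
#' @export
region_composition <- function(t, scheme = define_regions(t)) {
  stopifnot(inherits(t, "annotated_transcript"))
  rows <- lapply(c("five_prime", "rcds", "utr3"), function(r) {
    iv <- scheme[[r]]
    if (is.null(iv))
      return(data.frame(region = r, length = 0L,
                        A = NA_real_, C = NA_real_, G = NA_real_,
                        U = NA_real_))
    s <- substr(t$sequence, iv[1], iv[2])
    n <- nchar(s)
    cnt <- vapply(c("A", "C", "G", "U"),
                  function(b) lengths(regmatches(s, gregexpr(b, s, fixed = TRUE))),
                  integer(1))
    data.frame(region = r, length = n,
               A = cnt[["A"]] / n, C = cnt[["C"]] / n,
               G = cnt[["G"]] / n, U = cnt[["U"]] / n)
  })
  do.call(rbind, rows)
}

#' Read transcripts from FASTA plus an annotation table
#'
#' The annotation is a tab-separated file with header
#' \code{id<TAB>utr5_len<TAB>cds_end}; every FASTA record must have a
#' matching annotation row.
#'
#' @param fasta Path to a (multi-record, possibly line-wrapped) FASTA file.
#' @param annotation Path to the annotation TSV.
#' @return Named list of \code{annotated_transcript} objects.
#' @export
read_transcripts <- function(fasta, annotation) {
  seqs <- Biostrings::readBStringSet(fasta)
  ids <- sub("\\s.*$", "", names(seqs))
  ann <- utils::read.delim(annotation, stringsAsFactors = FALSE)
  need <- c("id", "utr5_len", "cds_end")
  if (!all(need %in% names(ann)))
    stop("annotation table must have columns id, utr5_len, cds_end")
  missing <- setdiff(ids, ann$id)
  if (length(missing))
    stop("no annotation for transcript(s): ", paste(missing, collapse = ", "))
  out <- lapply(seq_along(seqs), function(i) {
    a <- ann[match(ids[i], ann$id), ]
    annotated_transcript(ids[i], as.character(seqs[[i]]),
                         a$utr5_len, a$cds_end)
  })
  names(out) <- ids
  out
}

#' Write transcripts to FASTA plus an annotation table
#'
#' Inverse of \code{\link{read_transcripts}}; used by the shuffle and
#' fixture tooling.
#'
#' @param transcripts List of \code{annotated_transcript} objects.
#' @param fasta,annotation Output paths.
#' @return Invisibly, the list of paths.
#' @export
write_transcripts <- function(transcripts, fasta, annotation) {
  seqs <- Biostrings::BStringSet(vapply(transcripts, `[[`, "", "sequence"))
  names(seqs) <- vapply(transcripts, `[[`, "", "id")
  Biostrings::writeXStringSet(seqs, fasta)
  ann <- data.frame(id = names(seqs),
                    utr5_len = vapply(transcripts, `[[`, 0L, "utr5_len"),
                    cds_end = vapply(transcripts, `[[`, 0L, "cds_end"))
  utils::write.table(ann, annotation, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(fasta = fasta, annotation = annotation))
}
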