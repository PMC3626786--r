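#' Construct a base-pair table
#'
#' The pair table is the canonical machine representation of one secondary
#' structure: \code{partner[i]} is the 1-based partner of position i, or 0
#' if i is unpaired. The map must be an involution without self-pairs.
#' Crossing pairs (pseudoknots) are permitted in the table itself; only the
#' dot-bracket writer requires nestedness.
#'
#' @param partner Integer vector of partners (0 = unpaired).
#' @return Object of class \code{pair_table} with fields \code{n} and
#'   \code{partner}.
#' @export
pair_table <- function(partner) {
  partner <- as.integer(partner)
  pt <- structure(list(n = length(partner), partner = partner),
                  class = "pair_table")
  v <- validate_pair_table(pt)
  if (length(v)) stop("invalid pair table: ", paste(v, collapse = "; "))
  pt
}

#' Build a pair table from a list of (i, j) pairs
#'
#' @param pairs Two-column matrix or list of length-2 vectors.
#' @param n Sequence length.
#' @return A \code{pair_table}.
#' @export
pair_table_from_pairs <- function(pairs, n) {
  partner <- integer(n)
  if (is.list(pairs)) pairs <- do.call(rbind, pairs)
  if (!is.null(pairs) && length(pairs)) {
    for (r in seq_len(nrow(pairs))) {
      i <- pairs[r, 1]; j <- pairs[r, 2]
      partner[i] <- j; partner[j] <- i
    }
  }
  pair_table(partner)
}

#' Check pair-table invariants
#'
#' Reports, rather than throws: returns a character vector of violations
#' (empty iff the table is valid). Checked: partners within range, no
#' self-pairing, and the involution partner[partner[i]] == i.
#'
#' @param pt A \code{pair_table} (or a bare list with \code{n}, \code{partner}).
#' @return Character vector of violation messages.
#' @export
validate_pair_table <- function(pt) {
  p <- pt$partner
  n <- pt$n
  out <- character(0)
  bad <- which(p < 0L | p > n)
  if (length(bad))
    out <- c(out, sprintf("partner out of range at position %d", bad))
  selfp <- which(p == seq_len(n))
  if (length(selfp))
    out <- c(out, sprintf("self-pairing at position %d", selfp))
  ok <- setdiff(which(p > 0L & p <= n), selfp)
  asym <- ok[p[p[ok]] != ok]
  if (length(asym))
    out <- c(out, sprintf("asymmetric pair at position %d (partner %d)",
                          asym, p[asym]))
  out
}

#' @export
print.pair_table <- function(x, ...) {
  cat(sprintf("<pair_table> %d nt, %d base pairs\n",
              x$n, sum(x$partner > 0) %/% 2))
  invisible(x)
}

#' Parse dot-bracket notation into a pair table
#'
#' Accepts the Vienna characters \code{. ( )} plus the extended bracket
#' pairs \code{[] {} <>} for pseudoknotted input; each bracket family is
#' matched with its own stack.
#'
#' @param line Dot-bracket string.
#' @return A \code{pair_table}.
#' @examples
#' parse_dot_bracket("((..))")
#' @export
parse_dot_bracket <- function(line) {
  stopifnot(is.character(line), length(line) == 1L)
  ch <- strsplit(line, "")[[1]]
  openers <- c("(" = ")", "[" = "]", "{" = "}", "<" = ">")
  closers <- names(openers)
  names(closers) <- openers
  partner <- integer(length(ch))
  stacks <- list()
  for (i in seq_along(ch)) {
    c_i <- ch[i]
    if (c_i == ".") next
    if (c_i %in% names(openers)) {
      stacks[[c_i]] <- c(stacks[[c_i]], i)
    } else if (c_i %in% openers) {
      op <- closers[[c_i]]
      st <- stacks[[op]]
      if (is.null(st) || !length(st))
        stop(sprintf("unbalanced '%s' at position %d", c_i, i))
      j <- st[length(st)]
      stacks[[op]] <- st[-length(st)]
      partner[i] <- j
      partner[j] <- i
    } else {
      stop(sprintf("invalid character '%s' at position %d", c_i, i))
    }
  }
  left <- unlist(stacks)
  if (length(left))
    stop(sprintf("unbalanced '%s' at position %d",
                 ch[min(left)], min(left)))
  pair_table(partner)
}

#' Write a pair table as dot-bracket notation
#'
#' Only nested (pseudoknot-free) structures can be expressed with a single
#' bracket family; crossing pairs are rejected.
#'
#' @param pt A \code{pair_table}.
#' @return Dot-bracket string; \code{parse_dot_bracket(write_dot_bracket(pt))}
#'   reproduces \code{pt}.
#' @export
write_dot_bracket <- function(pt) {
  p <- pt$partner
  out <- rep(".", pt$n)
  open <- which(p > seq_len(pt$n))
  # crossing check: pairs (i,j), (k,l) with i<k<j<l cannot be nested
  if (length(open) > 1) {
    for (a in seq_along(open)) {
      i <- open[a]; j <- p[i]
      k <- open[open > i & open < j]
      if (any(p[k] > j))
        stop(sprintf("crossing pairs: (%d,%d) and (%d,%d)",
                     i, j, k[p[k] > j][1], p[k[p[k] > j][1]]))
    }
  }
  out[open] <- "("
  out[p[open]] <- ")"
  paste(out, collapse = "")
}

structure_record <- function(pt, free_energy = NA_real_, window_offset = 0L,
                             transcript_id = NA_character_, rank = 1L,
                             bases = NULL) {
  structure(list(pair_table = pt, free_energy = free_energy,
                 window_offset = as.integer(window_offset),
                 transcript_id = transcript_id, rank = as.integer(rank),
                 bases = bases),
            class = "structure_record")
}

#' @export
print.structure_record <- function(x, ...) {
  cat(sprintf("<structure_record> %s offset %d rank %d: %d nt, %d bp, dG %s\n",
              x$transcript_id, x$window_offset, x$rank, x$pair_table$n,
              sum(x$pair_table$partner > 0) %/% 2,
              ifelse(is.na(x$free_energy), "NA",
                     sprintf("%.2f", x$free_energy))))
  invisible(x)
}

#' Parse a CT (connect-table) structure file
#'
#' Reads the Mfold CT dialect: a header line starting with the nucleotide
#' count and optionally carrying an energy (any \code{dG} token followed by
#' a number), then one line per nucleotide with fields
#' \code{index base prev next partner index}. Several concatenated records
#' per file are supported and returned ranked in file order, mirroring an
#' ensemble of optimal and suboptimal structures from one fold. The
#' involution of the pair map is enforced; asymmetry, index gaps or count
#' mismatches are rejected with the offending line number.
#'
#' @param path Path to a CT file (possibly concatenated records).
#' @param transcript_id,window_offset Metadata attached to each record.
#' @return List of \code{structure_record}s; each carries the base letters
#'   from the file in \code{$bases} for cross-checking against the window
#'   sequence.
#' @export
parse_ct <- function(path, transcript_id = NA_character_,
                     window_offset = 0L) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  recs <- list()
  lineno <- 0L
  i <- 1L
  while (i <= length(lines)) {
    header <- trimws(lines[i])
    n <- suppressWarnings(as.integer(strsplit(header, "\\s+")[[1]][1]))
    if (is.na(n) || n < 1L)
      stop(sprintf("line %d: expected CT header starting with a count", i))
    energy <- NA_real_
    em <- regmatches(header,
                     regexpr("dG\\s*=?\\s*-?[0-9]+\\.?[0-9]*", header))
    if (length(em))
      energy <- as.numeric(regmatches(em, regexpr("-?[0-9]+\\.?[0-9]*", em)))
    if (i + n > length(lines))
      stop(sprintf("line %d: record declares %d nucleotides but file ends early",
                   i, n))
    body <- lines[(i + 1L):(i + n)]
    fields <- strsplit(trimws(body), "\\s+")
    partner <- integer(n)
    bases <- character(n)
    for (k in seq_len(n)) {
      f <- fields[[k]]
      lineno <- i + k
      if (length(f) < 5L)
        stop(sprintf("line %d: expected at least 5 CT columns", lineno))
      idx <- suppressWarnings(as.integer(f[1]))
      if (is.na(idx) || idx != k)
        stop(sprintf("line %d: index %s out of sequence (expected %d)",
                     lineno, f[1], k))
      bases[k] <- toupper(f[2])
      partner[k] <- suppressWarnings(as.integer(f[5]))
      if (is.na(partner[k]) || partner[k] < 0L || partner[k] > n)
        stop(sprintf("line %d: partner %s out of range", lineno, f[5]))
    }
    paired <- which(partner > 0L)
    bad <- paired[partner[partner[paired]] != paired | partner[paired] == paired]
    if (length(bad))
      stop(sprintf("line %d: partner asymmetry at position %d (partner %d)",
                   i + bad[1], bad[1], partner[bad[1]]))
    recs[[length(recs) + 1L]] <- structure_record(
      pair_table(partner), free_energy = energy,
      window_offset = window_offset, transcript_id = transcript_id,
      rank = length(recs) + 1L, bases = paste(bases, collapse = ""))
    i <- i + n + 1L
  }
  recs
}

#' Write structure records as a (possibly concatenated) CT file
#'
#' Emits the Mfold CT column layout consumed by \code{\link{parse_ct}}.
#'
#' @param records List of \code{structure_record}s (or a single one).
#' @param seqs Character vector of window sequences, one per record.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_ct <- function(records, seqs, path) {
  if (inherits(records, "structure_record")) records <- list(records)
  stopifnot(length(records) == length(seqs))
  con <- file(path, "w")
  on.exit(close(con))
  for (r in seq_along(records)) {
    rec <- records[[r]]
    n <- rec$pair_table$n
    stopifnot(nchar(seqs[r]) == n)
    hdr <- if (is.na(rec$free_energy)) sprintf("%d  structure %d", n, r)
           else sprintf("%d  dG = %.2f  structure %d", n, rec$free_energy, r)
    writeLines(hdr, con)
    bases <- strsplit(seqs[r], "")[[1]]
    p <- rec$pair_table$partner
    writeLines(sprintf("%d %s %d %d %d %d", seq_len(n), bases,
                       seq_len(n) - 1L,
                       ifelse(seq_len(n) == n, 0L, seq_len(n) + 1L),
                       p, seq_len(n)), con)
  }
  invisible(path)
}

#' Read dot-bracket structures from a file
#'
#' One structure per line, Vienna style; a line over the RNA alphabet
#' immediately preceding a structure line is taken as its sequence, and
#' a trailing \code{(-12.30)} energy annotation is honoured.
#'
#' @param path Path to a dot-bracket file.
#' @param transcript_id,window_offset Metadata attached to each record.
#' @return List of \code{structure_record}s.
#' @export
parse_dot_bracket_file <- function(path, transcript_id = NA_character_,
                                   window_offset = 0L) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, ">")]
  recs <- list()
  bases <- NULL
  for (ln in lines) {
    if (grepl("^[ACGUTacgut]+$", ln)) { bases <- toupper(chartr("T", "U", ln)); next }
    energy <- NA_real_
    em <- regmatches(ln, regexpr("\\(\\s*-?[0-9]+\\.?[0-9]*\\s*\\)\\s*$", ln))
    if (length(em)) {
      energy <- as.numeric(gsub("[()\\s]", "", em, perl = TRUE))
      ln <- trimws(sub("\\(\\s*-?[0-9]+\\.?[0-9]*\\s*\\)\\s*$", "", ln))
    }
    recs[[length(recs) + 1L]] <- structure_record(
      parse_dot_bracket(ln), free_energy = energy,
      window_offset = window_offset, transcript_id = transcript_id,
      rank = length(recs) + 1L, bases = bases)
    bases <- NULL
  }
  recs
}
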