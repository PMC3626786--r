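# Independent brute-force oracles and random-structure generators.
# These deliberately re-derive helices and motif selection from first
# principles (hash of pairs + chain following + manual run splitting) so
# that the package's linear-scan implementation is checked against a
# different algorithm.

oracle_helices <- function(pt) {
  p <- pt$partner
  ii <- which(p > seq_along(p))
  pairset <- new.env(parent = emptyenv())
  for (i in ii) assign(as.character(i), p[i], envir = pairset)
  has_pair <- function(i, j) {
    if (i < 1) return(FALSE)
    v <- mget(as.character(i), envir = pairset,
              ifnotfound = list(NA_integer_))[[1]]
    !is.na(v) && v == j
  }
  starts <- ii[!vapply(ii, function(i) has_pair(i - 1L, p[i] + 1L),
                       logical(1))]
  lapply(sort(starts), function(i) {
    j <- p[i]
    chain <- list(c(i, j))
    while (has_pair(i + 1L, j - 1L)) {
      i <- i + 1L; j <- j - 1L
      chain[[length(chain) + 1L]] <- c(i, j)
    }
    m <- do.call(rbind, chain)
    dimnames(m) <- list(NULL, c("i", "j"))
    m
  })
}

oracle_pair_class <- function(b1, b2) {
  k <- paste0(b1, b2)
  if (k %in% c("GC", "CG")) "GC"
  else if (k %in% c("AU", "UA")) "AU"
  else if (k %in% c("GU", "UG")) "GU"
  else NA_character_
}

oracle_select <- function(pt, wseq, crit) {
  b <- strsplit(wseq, "")[[1]]
  empty <- data.frame(class = character(), i1 = integer(), ik = integer(),
                      jk = integer(), j1 = integer(), length_bp = integer(),
                      strand_distance = integer(),
                      linker_paired = integer(), stringsAsFactors = FALSE)
  res <- list()
  for (hp in oracle_helices(pt)) {
    units <- list()
    if (crit$composition_class == "any") {
      units <- list(list(pairs = hp, tag = "general"))
    } else {
      cls <- mapply(oracle_pair_class, b[hp[, 1]], b[hp[, 2]])
      start <- 1L
      for (m in seq_len(nrow(hp))) {
        if (m == nrow(hp) || cls[m + 1L] != cls[m]) {
          if (cls[start] == crit$composition_class) {
            tag <- if (crit$hairpin_mode)
              paste0(crit$composition_class, "_stem")
            else crit$composition_class
            units[[length(units) + 1L]] <-
              list(pairs = hp[start:m, , drop = FALSE], tag = tag)
          }
          start <- m + 1L
        }
      }
    }
    for (u in units) {
      k <- nrow(u$pairs)
      if (k < crit$min_len_bp) next
      ik <- u$pairs[k, 1]; jk <- u$pairs[k, 2]
      d <- jk - ik - 1L
      lp <- if (d > 0L) sum(pt$partner[(ik + 1L):(jk - 1L)] > 0L) else 0L
      if (crit$hairpin_mode) {
        if (d >= crit$min_strand_distance) next
      } else {
        if (d < crit$min_strand_distance) next
        if (lp < crit$min_linker_paired) next
      }
      res[[length(res) + 1L]] <- data.frame(
        class = u$tag, i1 = u$pairs[1, 1], ik = ik, jk = jk,
        j1 = u$pairs[1, 2], length_bp = k, strand_distance = d,
        linker_paired = lp, stringsAsFactors = FALSE)
    }
  }
  if (!length(res)) return(empty)
  out <- do.call(rbind, res)
  out[order(out$i1, out$jk), , drop = FALSE]
}

# Random pair table: a handful of planted helices plus isolated (possibly
# crossing) pairs. Exercises distance-0 innermost pairs and pseudoknots.
random_pair_table <- function(n) {
  p <- integer(n)
  free <- rep(TRUE, n)
  for (attempt in seq_len(sample(0:6, 1))) {
    len <- sample(1:10, 1)
    ij <- sort(sample(seq_len(n), 2))
    i <- ij[1]; j <- ij[2]
    if (j - i < 2L * len - 1L) next
    idx <- c(i:(i + len - 1L), (j - len + 1L):j)
    if (!all(free[idx])) next
    p[i:(i + len - 1L)] <- j:(j - len + 1L)
    p[j:(j - len + 1L)] <- i:(i + len - 1L)
    free[idx] <- FALSE
  }
  for (attempt in seq_len(sample(0:4, 1))) {
    cand <- which(free)
    if (length(cand) < 2L) break
    ij <- sort(sample(cand, 2))
    p[ij[1]] <- ij[2]; p[ij[2]] <- ij[1]
    free[ij] <- FALSE
  }
  pair_table(p)
}

# Random sequence compatible with a pair table: paired positions get a
# random canonical/wobble combination, the rest is uniform ACGU.
random_seq_for <- function(pt) {
  n <- pt$n
  b <- sample(c("A", "C", "G", "U"), n, replace = TRUE)
  combos <- list(c("G", "C"), c("C", "G"), c("A", "U"), c("U", "A"),
                 c("G", "U"), c("U", "G"))
  for (i in which(pt$partner > seq_len(n))) {
    cc <- combos[[sample(6, 1)]]
    b[i] <- cc[1]
    b[pt$partner[i]] <- cc[2]
  }
  paste(b, collapse = "")
}

# Random nested (pseudoknot-free) pair table via recursive interval
# construction -- independent of both the parser and the writer.
random_nested_pairs <- function(lo, hi) {
  pairs <- NULL
  i <- lo
  while (i <= hi) {
    if (hi - i >= 1L && stats::runif(1) < 0.4) {
      j <- if (i + 1L == hi) hi else sample(seq(i + 1L, hi), 1)
      pairs <- rbind(pairs, c(i, j))
      if (j - i > 1L) pairs <- rbind(pairs, random_nested_pairs(i + 1L, j - 1L))
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  pairs
}

random_nested_pt <- function(n) {
  pair_table_from_pairs(random_nested_pairs(1L, n), n)
}

# Backend returning k all-unpaired structures with zero energy; the
# simplest contract-conforming ensemble backend.
unpaired_backend <- function() {
  folding_backend("unpaired", function(seq, k, transcript_id, offset) {
    lapply(seq_len(k), function(r)
      structure_record(pair_table(integer(nchar(seq))), free_energy = 0))
  })
}

random_transcript <- function(n, utr5_len = n %/% 5, cds_end = (n * 4L) %/% 5L,
                              id = "rand") {
  annotated_transcript(id, paste(sample(c("A", "C", "G", "U"), n,
                                        replace = TRUE), collapse = ""),
                       utr5_len, cds_end)
}
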