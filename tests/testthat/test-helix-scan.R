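test_that("maximal helices are enumerated with strict stacking", {
  h <- enumerate_helices(parse_dot_bracket("((((....))))"))
  expect_length(h, 1)
  expect_equal(h[[1]]$length_bp, 4L)
  expect_equal(h[[1]]$strand5, c(1L, 4L))
  expect_equal(h[[1]]$strand3, c(9L, 12L))
  # stacking broken between positions 3 and 6 -> two helices (3 bp, 2 bp)
  pt <- pair_table_from_pairs(
    rbind(c(1, 20), c(2, 19), c(3, 18), c(6, 14), c(7, 13)), 20)
  h2 <- enumerate_helices(pt)
  expect_length(h2, 2)
  expect_equal(vapply(h2, `[[`, 0L, "length_bp"), c(3L, 2L))
  expect_equal(h2[[2]]$pairs[, "i"], 6:7)
  expect_equal(enumerate_helices(pair_table(integer(30))), list())
  # partition: helix lengths sum to the number of pairs
  set.seed(21)
  for (rep in 1:50) {
    ptr <- random_pair_table(sample(20:200, 1))
    hs <- enumerate_helices(ptr)
    expect_equal(sum(vapply(hs, `[[`, 0L, "length_bp")),
                 sum(ptr$partner > 0) / 2)
    got <- lapply(hs, `[[`, "pairs")
    expect_equal(got, oracle_helices(ptr))
  }
})

test_that("strand distance is the gap inside the innermost pair", {
  h <- enumerate_helices(parse_dot_bracket("((((((((....))))))))"))[[1]]
  expect_equal(h$length_bp, 8L)
  expect_equal(strand_distance(h), 4L)  # hairpin loop size
  far <- enumerate_helices(pair_table_from_pairs(
    cbind(1:8, 100:93), 100))[[1]]
  expect_equal(strand_distance(far), 84L)
  # a hairpin with loop < 40 fails the non-hairpin filter
  expect_true(strand_distance(h) < 40)
})

test_that("linker paired counts include partners outside the linker", {
  pt <- parse_dot_bracket("((((((((....))))))))")
  h <- enumerate_helices(pt)[[1]]
  expect_equal(linker_paired_count(h, pt), 0L)  # unpaired loop
  # 8-bp internal hairpin in the linker: 16 paired linker nucleotides
  px <- plant_duplex_sequence(9, 100, 16, "GC", 400, seed = 4)
  pt2 <- planted_backend(px$truth)$fold(px$transcript$sequence, 1,
                                        px$truth$transcript_id, 0)[[1]]$pair_table
  hs <- enumerate_helices(pt2)
  main <- hs[[which(vapply(hs, `[[`, 0L, "length_bp") == 9L)]]
  expect_equal(linker_paired_count(main, pt2), 16L)
  # crossing partner outside the linker still counts the linker position
  pt3 <- pair_table_from_pairs(rbind(c(2, 10), c(5, 14)), 15)
  h3 <- enumerate_helices(pt3)[[1]]  # pair (2,10)
  expect_equal(h3$pairs[1, ], c(i = 2L, j = 10L))
  expect_equal(linker_paired_count(h3, pt3), 1L)
  # exhaustive oracle on random structures
  set.seed(31)
  for (rep in 1:30) {
    ptr <- random_pair_table(sample(30:150, 1))
    for (hh in enumerate_helices(ptr)) {
      lo <- hh$strand5[2]; hi <- hh$strand3[1]
      brute <- sum(vapply(seq_len(ptr$n), function(p)
        p > lo && p < hi && ptr$partner[p] != 0L, logical(1)))
      expect_equal(linker_paired_count(hh, ptr), brute)
    }
  }
})

test_that("composition sub-runs partition a helix by uniform pair class", {
  mk <- function(db, seq) {
    h <- enumerate_helices(parse_dot_bracket(db))[[1]]
    composition_subruns(h, seq)
  }
  # 9 all-GC pairs -> single GC run
  subs <- mk(paste0(strrep("(", 9), "....", strrep(")", 9)),
             paste0(strrep("G", 9), "....", strrep("C", 9)))
  expect_length(subs, 1)
  expect_equal(attr(subs[[1]], "class_tag"), "GC")
  expect_equal(subs[[1]]$length_bp, 9L)
  # classes GC,GC,AU,GC -> runs of 2,1,1
  subs2 <- mk("((((....))))", "GGAG....CUCC")
  expect_equal(vapply(subs2, `[[`, 0L, "length_bp"), c(2L, 1L, 1L))
  expect_equal(vapply(subs2, attr, "", "class_tag"), c("GC", "AU", "GC"))
  # wobble G:U breaks a GC run
  subs3 <- mk("((((....))))", "GGGG....CUCC")
  expect_equal(vapply(subs3, attr, "", "class_tag"), c("GC", "GU", "GC"))
  # non-complementary pair is corrupt input
  h <- enumerate_helices(parse_dot_bracket("((..))"))[[1]]
  expect_error(composition_subruns(h, "GAAAGC"), "non-complementary")
  # random property: sub-run lengths sum to k and match per-pair tags
  set.seed(41)
  for (rep in 1:30) {
    ptr <- random_pair_table(sample(30:120, 1))
    sq <- random_seq_for(ptr)
    b <- strsplit(sq, "")[[1]]
    for (hh in enumerate_helices(ptr)) {
      ss <- composition_subruns(hh, sq)
      expect_equal(sum(vapply(ss, `[[`, 0L, "length_bp")), hh$length_bp)
      tags <- unlist(lapply(ss, function(s)
        rep(attr(s, "class_tag"), s$length_bp)))
      per_pair <- mapply(oracle_pair_class, b[hh$pairs[, 1]],
                         b[hh$pairs[, 2]])
      expect_equal(tags, unname(per_pair))
      # runs are maximal: adjacent sub-runs never share a class
      rt <- vapply(ss, attr, "", "class_tag")
      if (length(rt) > 1)
        expect_true(all(rt[-1] != rt[-length(rt)]))
    }
  }
})

test_that("motif selection applies length, distance and linker thresholds", {
  crit_gc <- helix_criteria(composition_class = "GC")
  # planted 9-bp all-GC duplex, strands 100 nt apart, 20 paired linker nt
  px <- plant_duplex_sequence(9, 100, 20, "GC", 400, seed = 7)
  be <- planted_backend(px$truth)
  rec <- be$fold(px$transcript$sequence, 1, px$truth$transcript_id, 0)[[1]]
  m <- select_motifs(rec, px$transcript$sequence, crit_gc)
  expect_equal(nrow(m), 1L)
  expect_equal(m$class, "GC")
  expect_equal(c(m$i1, m$ik), px$truth$strand5)
  expect_equal(c(m$jk, m$j1), px$truth$strand3)
  # strands 30 nt apart: excluded as GC-helix, captured as GC-stem
  px2 <- plant_duplex_sequence(9, 30, 20, "GC", 400, seed = 8)
  rec2 <- planted_backend(px2$truth)$fold(px2$transcript$sequence, 1,
                                          px2$truth$transcript_id, 0)[[1]]
  expect_equal(nrow(select_motifs(rec2, px2$transcript$sequence, crit_gc)), 0L)
  stem <- select_motifs(rec2, px2$transcript$sequence,
                        helix_criteria(composition_class = "GC",
                                       hairpin_mode = TRUE))
  expect_true("GC_stem" %in% stem$class)
  expect_true(any(stem$i1 == px2$truth$strand5[1] & stem$length_bp == 9L))
  # 7-bp GC duplex at distance 100: too short
  px3 <- plant_duplex_sequence(7, 100, 20, "GC", 400, seed = 9)
  rec3 <- planted_backend(px3$truth)$fold(px3$transcript$sequence, 1,
                                          px3$truth$transcript_id, 0)[[1]]
  expect_equal(nrow(select_motifs(rec3, px3$transcript$sequence, crit_gc)), 0L)
  # class scans require the window sequence
  expect_error(select_motifs(rec, NULL, crit_gc), "sequence required")
})

test_that("scanner agrees with the brute-force oracle across criteria", {
  set.seed(51)
  crits <- list(helix_criteria(min_len_bp = 2, min_strand_distance = 5,
                               min_linker_paired = 1),
                helix_criteria(min_len_bp = 3, min_strand_distance = 10,
                               min_linker_paired = 2,
                               composition_class = "GC"),
                helix_criteria(min_len_bp = 2, min_strand_distance = 8,
                               composition_class = "AU",
                               hairpin_mode = TRUE))
  for (rep in 1:60) {
    ptr <- random_pair_table(sample(30:200, 1))
    sq <- random_seq_for(ptr)
    rec <- structure_record(ptr)
    for (crit in crits) {
      got <- select_motifs(rec, sq, crit)
      got <- got[order(got$i1, got$jk), , drop = FALSE]
      want <- oracle_select(ptr, sq, crit)
      rownames(got) <- rownames(want) <- NULL
      expect_equal(got, want)
    }
  }
})

test_that("raising any threshold never increases the motif count", {
  set.seed(61)
  for (rep in 1:20) {
    ptr <- random_pair_table(sample(50:200, 1))
    sq <- random_seq_for(ptr)
    rec <- structure_record(ptr)
    base <- helix_criteria(min_len_bp = 2, min_strand_distance = 4,
                           min_linker_paired = 0)
    n0 <- nrow(select_motifs(rec, sq, base))
    for (tweak in list(c(1, 0, 0), c(0, 4, 0), c(0, 0, 2))) {
      up <- helix_criteria(min_len_bp = base$min_len_bp + tweak[1],
                           min_strand_distance = base$min_strand_distance + tweak[2],
                           min_linker_paired = base$min_linker_paired + tweak[3])
      expect_lte(nrow(select_motifs(rec, sq, up)), n0)
    }
  }
})
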