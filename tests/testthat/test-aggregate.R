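local_motif_df <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r)
    data.frame(class = r$class, i1 = r$i1, ik = r$ik, jk = r$jk, j1 = r$j1,
               length_bp = r$ik - r$i1 + 1L,
               strand_distance = r$jk - r$ik - 1L,
               linker_paired = 0L, stringsAsFactors = FALSE)))
}

test_that("global mapping shifts coordinates and checks bounds", {
  m <- local_motif_df(list(class = "GC", i1 = 12, ik = 19, jk = 103, j1 = 110))
  g <- map_to_global(m, 400)
  expect_equal(c(g$i1, g$ik, g$jk, g$j1), c(412, 419, 503, 510))
  expect_equal(map_to_global(m, 0), m)
  expect_error(map_to_global(m, 400, transcript_length = 500), "bounds")
  # round trip on random motifs
  set.seed(71)
  for (rep in 1:25) {
    i1 <- sample(1:50, 1); ik <- i1 + sample(0:10, 1)
    jk <- ik + sample(2:100, 1); j1 <- jk + (ik - i1)
    mm <- local_motif_df(list(class = "general", i1 = i1, ik = ik,
                              jk = jk, j1 = j1))
    off <- sample(0:1000, 1)
    expect_equal(map_to_global(map_to_global(mm, off), -off), mm)
  }
})

test_that("deduplication counts support and eligible structures per key", {
  # same motif reported from 12 of 14 structures whose window spans it
  recs <- lapply(1:14, function(s)
    structure_record(pair_table(integer(200)), window_offset = (s - 1) * 10))
  cand <- do.call(rbind, lapply(1:12, function(s) {
    m <- local_motif_df(list(class = "GC", i1 = 140, ik = 147, jk = 190,
                             j1 = 197))
    m$structure_key <- s
    m
  }))
  # windows: [10s-9, 10s+190]; all 14 span [140,197]
  d <- deduplicate_motifs(cand, recs)
  expect_equal(nrow(d), 1L)
  expect_equal(d$support, 12L)
  expect_equal(d$eligible, 14L)
  expect_equal(d$support_fraction, 12 / 14)
  # two helices offset by 1 nt stay distinct (exact-identity rule)
  cand2 <- rbind(cand[1, ],
                 transform(cand[1, ], i1 = 141, ik = 148, jk = 191, j1 = 198))
  d2 <- deduplicate_motifs(cand2, recs)
  expect_equal(nrow(d2), 2L)
  expect_equal(d2$support, c(1L, 1L))
  # empty input
  expect_equal(nrow(deduplicate_motifs(cand[0, ], recs)), 0L)
  # union of supports equals the number of (structure, key) incidences
  expect_equal(sum(d2$support), nrow(cand2))
})

test_that("motif region and start-codon distance follow the 5'-strand start", {
  t <- annotated_transcript("t", strrep("A", 2500), 300, 1800)
  s <- define_regions(t)  # five_prime [1,500]
  m <- local_motif_df(list(class = "GC", i1 = 500, ik = 507, jk = 560, j1 = 567),
                      list(class = "GC", i1 = 501, ik = 508, jk = 561, j1 = 568),
                      list(class = "GC", i1 = 495, ik = 510, jk = 560, j1 = 575))
  expect_equal(assign_motif_region(m, s), c("five_prime", "rcds", "five_prime"))
  expect_equal(distance_from_start_codon(
    data.frame(i1 = c(21, 101, 301)), utr5_len = 100), c(-80L, 0L, 200L))
})

test_that("per-100-nt frequencies normalize by region length and pool correctly", {
  mk <- function(id, L, utr5, cds) annotated_transcript(id, strrep("A", L),
                                                        utr5, cds)
  t1 <- mk("a", 1000, 100, 900)  # five_prime 300, rcds 600, utr3 100
  motifs <- data.frame(
    transcript_id = c("a", "a"), class = "GC",
    region = c("five_prime", "five_prime"),
    strand_distance = c(100L, 260L), length_bp = c(8L, 10L),
    stringsAsFactors = FALSE)
  f <- frequency_per_100nt(motifs, list(t1))
  fp <- f[f$transcript_id == "a" & f$region == "five_prime", ]
  expect_equal(fp$count, 2L)
  expect_equal(fp$freq_per_100nt, 2 / 300 * 100)
  expect_equal(f[f$transcript_id == "a" & f$region == "whole", "count"], 2L)
  # pooled: two transcripts, 4 motifs over 1000+1000 nt of whole length
  t2 <- mk("b", 1000, 100, 900)
  motifs2 <- rbind(motifs, transform(motifs, transcript_id = "b"))
  f2 <- frequency_per_100nt(motifs2, list(t1, t2))
  pooled_whole <- f2[f2$transcript_id == "(pooled)" & f2$region == "whole", ]
  expect_equal(pooled_whole$count, 4L)
  expect_equal(pooled_whole$freq_per_100nt, 0.2)
  # per-region counts sum to the whole-transcript count
  for (id in c("a", "b", "(pooled)")) {
    sub <- f2[f2$transcript_id == id, ]
    expect_equal(sum(sub[sub$region != "whole", "count"]),
                 sub[sub$region == "whole", "count"])
  }
  # pooled frequency lies between per-transcript extremes (weighted mean)
  per <- f2[f2$transcript_id %in% c("a", "b") & f2$region == "whole",
            "freq_per_100nt"]
  expect_gte(pooled_whole$freq_per_100nt, min(per))
  expect_lte(pooled_whole$freq_per_100nt, max(per))
  # zero motifs
  f0 <- frequency_per_100nt(motifs[0, ], list(t1))
  expect_true(all(f0$count == 0L) && all(f0$freq_per_100nt == 0))
})

test_that("strand-distance statistics use the sample standard deviation", {
  motifs <- data.frame(class = "GC", strand_distance = c(100, 260),
                       length_bp = c(8L, 10L), stringsAsFactors = FALSE)
  st <- strand_distance_stats(motifs)
  expect_equal(st$mean_distance, 180)
  expect_equal(st$sd_distance, sqrt(((100 - 180)^2 + (260 - 180)^2) / 1))
  expect_equal(st$sd_distance, 113.137, tolerance = 1e-4)
  # single motif: SD reported as 0 and flagged
  st1 <- strand_distance_stats(motifs[1, ])
  expect_equal(st1$sd_distance, 0)
  expect_true(st1$single)
  # streaming-moments oracle on random groups
  set.seed(81)
  for (rep in 1:20) {
    n <- sample(2:40, 1)
    g <- data.frame(class = sample(c("GC", "AU"), n, replace = TRUE),
                    strand_distance = sample(40:400, n, replace = TRUE),
                    length_bp = sample(8:14, n, replace = TRUE))
    st2 <- strand_distance_stats(g)
    for (cl in unique(g$class)) {
      x <- g$strand_distance[g$class == cl]
      m1 <- sum(x) / length(x)
      m2 <- sum(x^2) / length(x)
      sd_stream <- if (length(x) < 2) 0 else
        sqrt((m2 - m1^2) * length(x) / (length(x) - 1))
      row <- st2[st2$class == cl, ]
      expect_equal(row$mean_distance, m1)
      expect_equal(row$sd_distance, sd_stream, tolerance = 1e-9)
    }
  }
  expect_equal(nrow(strand_distance_stats(motifs[0, ])), 0L)
})

test_that("report tables are deterministic and round-trip through read", {
  px <- plant_duplex_sequence(9, 100, 20, "GC", 1000, seed = 7,
                              duplex_start = 151, utr5_len = 100,
                              cds_end = 900)
  res <- scan_transcripts(list(px$transcript), planted_backend(px$truth),
                          helix_criteria(composition_class = "GC"),
                          window = 800, step = 20, structures = 1)
  f1 <- tempfile(); f2 <- tempfile()
  write_motif_table(res$motifs, f1)
  write_motif_table(res$motifs, f2)
  expect_identical(readLines(f1), readLines(f2))
  back <- utils::read.delim(f1, stringsAsFactors = FALSE)
  expect_equal(nrow(back), nrow(res$motifs))
  expect_equal(back$strand5_start, res$motifs$strand5_start)
  expect_equal(back$strand5_seq, res$motifs$strand5_seq)
  expect_equal(back$region, res$motifs$region)
  g1 <- tempfile(); g2 <- tempfile()
  write_region_table(res$frequencies, g1)
  write_region_table(res$frequencies, g2)
  expect_identical(readLines(g1), readLines(g2))
  backf <- utils::read.delim(g1, stringsAsFactors = FALSE)
  expect_equal(sum(backf$count[backf$region == "whole"]),
               2L * nrow(res$motifs))  # transcript row + pooled row
  # one motif -> header + one row
  expect_length(readLines(f1), 2L)
})
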