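test_that("effective intervals follow the INS terminating-coordinate rule", {
  r <- data.frame(pos = c(5000, 1001, 100), end = c(5000, 1100, 100),
                  svtype = c("INS", "DEL", "INS"), svlen = c(300, 100, 0))
  eff <- effective_interval(r)
  expect_equal(eff$start, c(4999, 1000, 99))
  expect_equal(eff$end, c(5299, 1100, 99))         # INS end = pos-1+svlen
  expect_equal(attr(eff, "degenerate"), c(FALSE, FALSE, TRUE))
  r2 <- data.frame(pos = 1, end = 1, svtype = "INS", svlen = NA_real_)
  expect_error(effective_interval(r2), "missing svlen")
})

test_that("rep-SV classification honours the 1-bp and 100-kbp boundaries", {
  reps <- repeat_track(c("chr1", "chr1", "chr1"),
                       c(1199, 900, 1050), c(1300, 980, 1250),
                       c("LINE/L1", "Bov-A2", "Bov-A2"))
  cs <- make_callset("chr1", c(1001, 200000, 500000), c(1200, 299999, 599999),
                     "DEL", c(200, 100000, 99999),
                     id = c("edge", "capped", "free"))
  cls <- classify_rep_sv(cs, reps)
  ## effective [1000,1200): 1 bp with LINE/L1 at [1199,1300), 150 bp Bov-A2
  edge <- cls[cls$id == "edge", ]
  expect_true(edge$is_rep)
  expect_equal(edge$rep_type, "Bov-A2")            # dominant by summed bp
  expect_equal(edge$overlap_bp, 150)
  expect_equal(edge$all_overlaps[[1]][["LINE/L1"]], 1)
  ## svlen = 100000 is NOT < 100 kbp -> nonrep even if overlapping
  reps2 <- repeat_track("chr1", 200050, 200150, "Bov-A2")
  cls2 <- classify_rep_sv(cs, reps2)
  expect_false(cls2$is_rep[cls2$id == "capped"])
  ## no overlap -> nonrep
  expect_false(cls$is_rep[cls$id == "free"])
})

test_that("dominant type ties break lexicographically", {
  reps <- repeat_track(c("chr1", "chr1"), c(100, 200), c(150, 250),
                       c("LTR/ERVK", "Bov-A2"))
  cs <- make_callset("chr1", 101, 250, "DEL", 150)
  cls <- classify_rep_sv(cs, reps)
  expect_equal(unname(cls$all_overlaps[[1]]), c(50, 50))
  expect_equal(cls$rep_type, "Bov-A2")
})

test_that("classification agrees with the all-pairs overlap oracle", {
  set.seed(99)
  n_sv <- 300; n_rep <- 300
  chroms <- c("c1", "c2")
  pos <- sample.int(5e4, n_sv) + 100
  svlen <- sample(50:2000, n_sv, replace = TRUE)
  svtype <- sample(c("DEL", "INS", "DUP"), n_sv, replace = TRUE)
  cs <- make_callset(sample(chroms, n_sv, TRUE), pos,
                     ifelse(svtype == "INS", pos, pos + svlen - 1),
                     svtype, svlen)
  rstart <- sample.int(5e4, n_rep)
  reps <- repeat_track(sample(chroms, n_rep, TRUE), rstart,
                       rstart + sample(20:3000, n_rep, TRUE),
                       sample(c("Bov-A2", "LINE/L1", "LTR/ERVK"), n_rep, TRUE))
  cls <- classify_rep_sv(cs, reps)
  eff <- effective_interval(cs$records)
  eff$chrom <- cs$records$chrom
  orc <- overlap_oracle(eff, reps)
  expect_equal(cls$is_rep, orc$total >= 1 & cs$records$svlen < 1e5)
  expect_equal(cls$rep_type, orc$rep_type)
  expect_equal(cls$overlap_bp, orc$dominant_bp)
})

test_that("evolutionary states follow the carrier-pattern definitions", {
  meta <- make_meta(n_t = 3, n_i = 3, n_h = 2)  # inds 1-3 t, 4-6 i, 7-8 h
  pat <- rbind(
    c(1, 0, 0, 1, 0, 0, 0, 0),   # 1 taurine + 1 indicine -> shared
    c(0, 0, 0, 1, 1, 0, 0, 0),   # 2 indicine -> private_indicine
    c(0, 0, 0, 0, 0, 0, 1, 0),   # 1 hybrid only -> specific
    c(1, 1, 0, 0, 0, 0, 1, 0),   # 2 taurine + hybrid -> private_taurine
    c(1, 0, 0, 0, 0, 0, 1, 0),   # 1 taurine + 1 hybrid -> unassigned
    c(0, 0, 0, 0, 1, 0, 0, 0)    # singleton -> specific
  )
  storage.mode(pat) <- "integer"
  cs <- make_callset("chr1", seq(1000, by = 1000, length.out = 6),
                     seq(1000, by = 1000, length.out = 6) + 99,
                     "DEL", 100, gt = pat, samples = meta$individual)
  expect_equal(assign_state(cs, meta),
               c("shared", "private_indicine", "specific",
                 "private_taurine", "unassigned", "specific"))
  ## zero carriers is an upstream-filter violation
  pat0 <- pat; pat0[1, ] <- 0L
  cs0 <- make_callset("chr1", seq(1000, by = 1000, length.out = 6),
                      seq(1000, by = 1000, length.out = 6) + 99,
                      "DEL", 100, gt = pat0, samples = meta$individual)
  expect_error(assign_state(cs0, meta), "zero carriers")
})

test_that("genomic context uses exon > intron > intergenic priority", {
  genes <- gene_track(rep("chr1", 2), c(1000, 2000), c(5000, 2400),
                      c("gene", "exon"), c("g1", "g1"))
  cs <- make_callset("chr1", c(2101, 1201, 8001), c(2200, 1300, 8100),
                     "DEL", 100, id = c("in_exon", "in_intron", "outside"))
  ctx <- setNames(annotate_context(cs, genes), cs$records$id)
  expect_equal(ctx[c("in_exon", "in_intron", "outside")],
               c(in_exon = "exon", in_intron = "intron",
                 outside = "intergenic"))
})

test_that("composition matrices count carriers by dominant type and state", {
  meta <- make_meta(n_t = 2, n_i = 2)
  gt <- rbind(c(1L, 0L, 0L, 0L),    # specific, carried by ind_01
              c(1L, 1L, 1L, 0L),    # shared
              c(0L, 0L, 1L, 1L))    # private_indicine
  cs <- make_callset("chr1", c(1001, 3001, 5001), c(1100, 3100, 5100),
                     "DEL", 100, gt = gt, samples = meta$individual)
  reps <- repeat_track(rep("chr1", 3), c(1000, 3000, 5000),
                       c(1100, 3100, 5100),
                       c("Bov-A2", "Bov-A2", "LINE/L1"))
  ann <- annotate_cohort(cs, reps, meta)
  m_all <- composition_matrix(ann, cs, meta, "all")
  expect_equal(m_all["ind_01", "Bov-A2"], 2L)
  expect_equal(m_all["ind_04", "LINE/L1"], 1L)
  m_spec <- composition_matrix(ann, cs, meta, "specific")
  expect_equal(sum(m_spec), 1L)
  expect_equal(m_spec["ind_01", "Bov-A2"], 1L)
  ## state-restricted matrices partition the per-type totals
  m_shared <- composition_matrix(ann, cs, meta, "shared")
  m_priv <- composition_matrix(ann, cs, meta, "private")
  tot <- function(m, t) if (t %in% colnames(m)) sum(m[, t]) else 0L
  for (t in colnames(m_all))
    expect_equal(tot(m_all, t),
                 tot(m_shared, t) + tot(m_priv, t) + tot(m_spec, t))
  ## empty selection warns and returns a 0-column matrix
  ann2 <- ann; ann2$state <- "shared"
  expect_warning(m0 <- composition_matrix(ann2, cs, meta, "specific"), "empty")
  expect_equal(ncol(m0), 0)
})

test_that("size classes use half-open boundaries", {
  a <- data.frame(svlen = c(60, 300, 600))
  expect_equal(as.numeric(summarize_size_classes(a)), rep(1 / 3, 3))
  expect_equal(as.numeric(summarize_size_classes(data.frame(svlen = 5000))),
               c(0, 0, 1))
  expect_equal(unname(summarize_size_classes(data.frame(svlen = 200))["medium"]), 1)
  expect_error(summarize_size_classes(data.frame(svlen = 49)), "50")
})
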