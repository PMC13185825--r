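test_that("VCF parsing resolves types, lengths and skips unusable records", {
  f <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"t\">",
    "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"l\">",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"e\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"g\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1\ts2",
    "chr1\t1000\ta\tN\t<DEL>\t.\tPASS\tSVTYPE=DEL;SVLEN=-120;END=1119\tGT\t0/1\t0/0",
    "chr1\t5000\tb\tN\t<INS>\t.\tPASS\tSVTYPE=INS;SVLEN=300\tGT\t1/1\t./.",
    "chr1\t7000\tc\tN\t<DEL>\t.\tPASS\tSVTYPE=DEL;END=7099\tGT\t0/1\t0/1",
    "chr1\t9000\td\tN\tN]chr2:100]\t.\tPASS\tSVTYPE=BND\tGT\t0/1\t0/0",
    "chr2\t100\te\tN\t<DEL>\t.\tPASS\tSVTYPE=DEL\tGT\t0/1\t0/1"
  ), f)
  expect_warning(cs <- read_sv_vcf(f), "skipped")
  expect_equal(n_svs(cs), 3)                       # BND + no-length skipped
  expect_equal(attr(cs, "n_skipped_type"), 1)
  expect_equal(attr(cs, "n_skipped_len"), 1)
  r <- cs$records
  expect_equal(r$svlen[r$id == "a"], 120)          # absolute-value convention
  expect_equal(r$pos[r$id == "b"], 5000)
  expect_equal(r$svlen[r$id == "b"], 300)
  expect_equal(r$end[r$id == "b"], 5000)           # raw INS end = pos
  expect_equal(r$svlen[r$id == "c"], 100)          # from END when SVLEN absent
  ## genotype semantics: 0/0 absent, any alt present, ./. missing
  expect_equal(unname(cs$gt[r$id == "a", ]), c(1L, 0L))
  expect_equal(unname(cs$gt[r$id == "b", ]), c(2L, NA_integer_))
})

test_that("VCF write/read round-trip preserves all record fields and GT", {
  co <- simulate_cohort(cohort_config(seed = 11, n_sv = 120))
  f <- tempfile(fileext = ".vcf")
  write_sv_vcf(co$callset, f, genome = co$genome)
  back <- read_sv_vcf(f)
  expect_identical(co$callset$records[1:6], back$records[1:6])
  expect_identical(unname(co$callset$gt), unname(back$gt))
  expect_identical(co$callset$samples, back$samples)
})

test_that("repeat annotation dialects convert coordinates correctly", {
  ## rmout is 1-based inclusive, BED half-open; internal is 0-based half-open
  tr <- repeat_track(c("chr1", "chr1"), c(100, 99), c(200, 200),
                     c("LINE/L1", "Bov-A2"))
  fb <- tempfile(fileext = ".bed"); fo <- tempfile(fileext = ".out")
  write_repeat_annotation(tr, fb, "bed")
  write_repeat_annotation(tr, fo, "rmout")
  ## rmout line must carry begin = start + 1
  ln <- readLines(fo)[4]
  expect_match(ln, " 101 ")
  bb <- read_repeat_annotation(fb, "bed")
  oo <- read_repeat_annotation(fo, "rmout")
  expect_equal(as.data.frame(bb), as.data.frame(tr))
  expect_equal(as.data.frame(oo)[c("chrom", "start", "end", "rep_type")],
               as.data.frame(tr)[c("chrom", "start", "end", "rep_type")])
  ## overlapping features are both retained
  expect_equal(nrow(bb), 2)
  ## inverted intervals rejected with a line number
  writeLines("chr1\t500\t400\tBov-A2", fb)
  expect_error(read_repeat_annotation(fb, "bed"), "line 1")
})

test_that("merging clusters by breakpoint distance with type matching", {
  mk <- function(pos, end, svtype, svlen, src)
    make_callset("chr1", pos, end, svtype, svlen, source = src)
  ## two DELs, starts 10000/10500, ends 10300/10800, from 2 sources -> merged
  a <- mk(10000, 10300, "DEL", 301, "cuteSV")
  b <- mk(10500, 10800, "DEL", 301, "sniffles")
  m <- merge_callsets(list(a, b))
  expect_equal(n_svs(m), 1)
  expect_equal(m$records$pos, 10000)               # smallest-tuple representative
  ## DEL and INS at identical positions do not merge (and each lacks support)
  c1 <- mk(10000, 10300, "DEL", 301, "cuteSV")
  c2 <- mk(10000, 10000, "INS", 301, "sniffles")
  expect_equal(n_svs(merge_callsets(list(c1, c2), min_support = 1)), 2)
  expect_equal(n_svs(merge_callsets(list(c1, c2), min_support = 2)), 0)
  ## 49-bp DEL from 3 sources dropped by the length floor
  short <- lapply(c("a", "b", "c"), function(s) mk(100, 148, "DEL", 49, s))
  expect_equal(n_svs(merge_callsets(short, min_support = 2)), 0)
  ## >100 kbp dropped by the cap
  big <- lapply(c("a", "b"), function(s) mk(1e5, 2.1e5, "DEL", 100001, s))
  expect_equal(n_svs(merge_callsets(big)), 0)
  ## breakpoints 1001 bp apart do not merge
  far <- list(mk(10000, 10300, "DEL", 301, "a"), mk(11001, 11301, "DEL", 301, "b"))
  expect_equal(n_svs(merge_callsets(far, min_support = 2)), 0)
})

test_that("merged length is the lower median and support is tracked", {
  sets <- lapply(list(c("a", 300), c("b", 320), c("c", 340), c("d", 360)),
                 function(z) make_callset("chr1", 1000, 1000 + as.numeric(z[2]) - 1,
                                          "DEL", as.numeric(z[2]), source = z[1]))
  m <- merge_callsets(sets, min_support = 2)
  expect_equal(m$records$svlen, 320)               # lower median of 300,320,340,360
  expect_equal(m$records$support, "a,b,c,d")
})

test_that("merging is idempotent and invariant to input order", {
  set.seed(42)
  pos <- sort(sample(seq(1e4, 9e5, by = 5000), 40))
  mk <- function(jit, src) make_callset("chr1", pos + jit, pos + jit + 200,
                                        "DEL", 201, source = src)
  sets <- list(mk(0, "a"), mk(50, "b"), mk(-30, "c"))
  m1 <- merge_callsets(sets)
  m2 <- merge_callsets(rev(sets))
  expect_equal(m1$records[1:6], m2$records[1:6])
  again <- merge_callsets(list(m1), min_support = 1)
  expect_equal(n_svs(again), n_svs(m1))
})

test_that("missingness filter uses a strict > threshold", {
  gt <- rbind(c(NA, NA, NA, 0L),    # 0.75 missing -> removed
              c(NA, NA, 1L, 0L),    # 0.50 missing -> retained
              c(1L, 0L, 1L, 0L))    # none missing -> retained
  cs <- make_callset("chr1", c(100, 300, 500), c(199, 399, 599),
                     "DEL", c(100, 100, 100), gt = gt,
                     samples = paste0("s", 1:4))
  kept <- filter_missingness(cs, max_missing = 0.5)
  expect_equal(n_svs(kept), 2)
  expect_false("fx_001" %in% kept$records$id)
})

test_that("novelty requires 50% reciprocal overlap on effective intervals", {
  q <- make_callset(c("chr1", "chr1", "chr2"), c(101, 1101, 101),
                    c(200, 1200, 101),
                    c("DEL", "DEL", "INS"), c(100, 100, 100),
                    id = c("exact_half", "short_ov", "ins"))
  pub <- make_callset(c("chr1", "chr1", "chr2"), c(151, 1181, 151),
                      c(250, 1280, 151),
                      c("DEL", "DEL", "INS"), c(100, 100, 100),
                      id = c("p1", "p2", "p3"), source = "published")
  ## query [100,200) vs published [150,250): overlap 50 = 0.5 of both -> known
  part <- novelty_filter(q, pub)
  expect_true("exact_half" %in% part$known$records$id)
  ## [100,200) vs [180,280): overlap 20 -> novel
  expect_true("short_ov" %in% part$novel$records$id)
  ## INS pos=101 len=100 vs published INS pos=151 len=100:
  ## effective [100,200) vs [150,250) -> overlap 50 -> known
  expect_true("ins" %in% part$known$records$id)
})

test_that("saturation curves behave on degenerate call-set families", {
  one <- make_callset("chr1", seq(1e4, 5e4, by = 1e4),
                      seq(1e4, 5e4, by = 1e4) + 99, "DEL", 100)
  same <- list(one, one, one, one)
  s <- saturation_curve(same, n_reps = 5, seed = 1)
  expect_true(all(s$union_mean == 5))              # flat union
  expect_true(all(s$core_mean == 5))
  ## pairwise-disjoint: union grows linearly, core collapses
  disj <- lapply(0:2, function(i)
    make_callset("chr1", seq(1e5, 1.4e5, by = 1e4) + i * 5e4,
                 seq(1e5, 1.4e5, by = 1e4) + i * 5e4 + 99, "DEL", 100,
                 source = paste0("s", i)))
  s2 <- saturation_curve(disj, n_reps = 3, seed = 2)
  expect_equal(s2$union_mean, c(5, 10, 15))
  expect_equal(s2$core_mean[2:3], c(0, 0))
  ## determinism
  s3 <- saturation_curve(disj, n_reps = 3, seed = 2)
  expect_identical(s2, s3)
  expect_error(saturation_curve(disj, n_reps = 0), "n_reps")
})
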