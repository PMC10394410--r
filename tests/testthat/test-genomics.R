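write_bedgraph <- function(lines) {
  path <- withr::local_tempfile(fileext = ".bedGraph",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

test_that("bedGraph binning follows the per-base convention and strand", {
  path <- write_bedgraph(c("chr1\t100\t140\t5"))
  gene <- gene_annotation("chr1", tss = 100, tes = 200, strand = "+")
  prof <- read_profile(path, gene, bin_width = 20, flank_upstream = 0)
  expect_equal(prof$value, c(5, 5, 0, 0, 0))
  expect_equal(prof$pos, c(10, 30, 50, 70, 90))

  # minus-strand gene over the same interval: profile reversed
  gene_m <- gene_annotation("chr1", tss = 200, tes = 100, strand = "-")
  prof_m <- read_profile(path, gene_m, bin_width = 20, flank_upstream = 0)
  expect_equal(prof_m$value, rev(prof$value))
  expect_equal(prof_m$pos, c(10, 30, 50, 70, 90))

  # upstream flank shifts the TSS-relative coordinates
  path3 <- write_bedgraph(c("chr1\t60\t100\t2", "chr1\t100\t140\t5"))
  prof_f <- read_profile(path3, gene, bin_width = 20, flank_upstream = 40)
  expect_equal(prof_f$value, c(2, 2, 5, 5, 0, 0, 0))
  expect_equal(prof_f$pos[1], -30)
})

test_that("overlapping bedGraph records are summed, partial overlaps weighted", {
  path <- write_bedgraph(c("chr1\t100\t120\t1", "chr1\t100\t120\t2",
                           "chr1\t130\t140\t4"))
  gene <- gene_annotation("chr1", tss = 100, tes = 160, strand = "+")
  prof <- read_profile(path, gene, bin_width = 20, flank_upstream = 0)
  # bin 1: fully covered by 1 + 2; bin 2: half covered by 4 -> 2
  expect_equal(prof$value, c(3, 2, 0))
})

test_that("missing coverage yields a zero profile with a warning", {
  path <- write_bedgraph(c("chr2\t0\t50\t7"))
  gene <- gene_annotation("chr1", tss = 100, tes = 200, strand = "+")
  expect_warning(prof <- read_profile(path, gene, bin_width = 20,
                                      flank_upstream = 0), "no coverage")
  expect_true(all(prof$value == 0))
})

test_that("profiles round-trip through the tab-separated writer", {
  path <- write_bedgraph(c("chr1\t100\t180\t3.5"))
  gene <- gene_annotation("chr1", tss = 100, tes = 200, strand = "+",
                          symbol = "GENE1")
  prof <- read_profile(path, gene, bin_width = 20, flank_upstream = 0)
  out <- withr::local_tempfile(fileext = ".tsv")
  write_profile(prof, out)
  back <- read_profile(out, gene, format = "tsv", bin_width = 20,
                       flank_upstream = 0)
  expect_equal(back$value, prof$value)
  expect_equal(back$pos, prof$pos)
})

test_that("interpolation is exact at nodes, linear between, clamped outside", {
  x <- c(10, 30, 50)
  v <- c(2, 4, 1)
  expect_equal(interpolate_profile(x, v, 30), 4)
  expect_equal(interpolate_profile(x, v, 20), 3)     # midpoint of 2 and 4
  expect_equal(interpolate_profile(x, v, 100), 1)    # clamped right
  expect_equal(interpolate_profile(x, v, -5), 2)     # clamped left
  expect_error(interpolate_profile(10, 2, 5), "at least 2")
  expect_error(interpolate_profile(c(3, 1), c(1, 2), 2), "increasing")
})

test_that("metagene of a single gene is that gene's resampled profile", {
  pos <- seq(-500, 4000, by = 20)
  prof <- data.frame(pos = pos, rate = 1 + sin(pos / 300))
  mg <- metagene_average(list(prof), gene_lengths = 4000,
                         n_interior_points = 50, end_window = 1000)
  body <- mg[mg$segment == "body", ]
  at <- 1000 + body$pos * (4000 - 2000)
  expect_equal(body$rate, interpolate_profile(pos, prof$rate, at))
  tss <- mg[mg$segment == "tss", ]
  expect_equal(tss$rate, interpolate_profile(pos, prof$rate, tss$pos))
  expect_true(all(mg$rate_q25 == mg$rate & mg$rate_q75 == mg$rate))
})

test_that("metagene averages constants and matches an independent oracle", {
  p1 <- data.frame(pos = seq(-200, 2000 + 200, by = 20), rate = 1)
  p2 <- data.frame(pos = seq(-200, 4000 + 200, by = 20), rate = 3)
  mg <- metagene_average(list(p1, p2), gene_lengths = c(2000, 4000),
                         n_interior_points = 100, end_window = 500)
  expect_true(all(abs(mg$rate - 2) < 1e-12))

  # varying profiles: interior averaging against resample-then-mean
  set.seed(21)
  mk <- function(len) {
    pos <- seq(-200, len + 200, by = 20)
    data.frame(pos = pos, rate = exp(0.2 * sin(pos / 150)) + runif(1))
  }
  profs <- list(mk(3000), mk(4000))
  lens <- c(3000, 4000)
  mg2 <- metagene_average(profs, lens, n_interior_points = 100,
                          end_window = 1000)
  body <- mg2[mg2$segment == "body", ]
  expect_equal(body$rate,
               metagene_oracle_body(profs, lens, 100, 1000),
               tolerance = 1e-12)
})

test_that("metagene is permutation-invariant and linear in profiles", {
  mk <- function(len, amp) {
    pos <- seq(-100, len + 100, by = 20)
    data.frame(pos = pos, rate = amp * (1 + cos(pos / 120)))
  }
  a <- mk(2400, 1); b <- mk(3600, 2); c_ <- mk(3000, 0.5)
  lens <- c(2400, 3600, 3000)
  m1 <- metagene_average(list(a, b, c_), lens, 60, 800)
  m2 <- metagene_average(list(c_, a, b), lens[c(3, 1, 2)], 60, 800)
  expect_equal(m1$rate, m2$rate)

  # linearity: scaling every profile scales the mean curve
  sc <- lapply(list(a, b, c_), function(p) transform(p, rate = 3 * rate))
  m3 <- metagene_average(sc, lens, 60, 800)
  expect_equal(m3$rate, 3 * m1$rate)
})

test_that("genes shorter than twice the end window are excluded", {
  short <- data.frame(pos = seq(0, 1500, 20), rate = 1)
  long <- data.frame(pos = seq(0, 5000, 20), rate = 2)
  expect_warning(
    mg <- metagene_average(list(short, long), c(1500, 5000),
                           n_interior_points = 30, end_window = 1000),
    "excluded")
  expect_true(all(mg$rate == 2))
  expect_error(
    suppressWarnings(metagene_average(list(short), 1500,
                                      n_interior_points = 30,
                                      end_window = 1000)),
    "no gene")
})

test_that("annotations validate strand-coordinate consistency and parse BED", {
  expect_error(gene_annotation("chr1", 100, 100), "differ")
  expect_error(gene_annotation("chr1", 300, 100, "+"), "tss < tes")
  expect_error(gene_annotation("chr1", 100, 300, "-"), "tss > tes")

  bed <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t100\t500\tGENEA\t0\t+",
               "chr2\t2000\t2600\tGENEB\t0\t-"), bed)
  ann <- read_annotations(bed)
  expect_equal(ann$GENEA$tss, 100)
  expect_equal(ann$GENEA$tes, 500)
  expect_equal(ann$GENEB$tss, 2600)
  expect_equal(ann$GENEB$tes, 2000)
  expect_equal(ann$GENEB$strand, "-")
})
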