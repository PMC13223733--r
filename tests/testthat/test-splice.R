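test_that("regulated / non-regulated / ambiguous stratification rules", {
  expect_equal(classify_regulated(list(dpsi = c(10, -10),
                                       probability = 0.9)), "regulated")
  expect_equal(classify_regulated(list(dpsi = c(1, -1),
                                       probability = 0)), "non_regulated")
  expect_equal(classify_regulated(list(dpsi = c(10, -10),
                                       probability = 0.3)), "ambiguous")
  ## the 2-5% deltaPSI gap is ambiguous even at probability 0
  expect_equal(classify_regulated(list(dpsi = c(3, -3),
                                       probability = 0)), "ambiguous")
  ## probability boundary: exactly 0.5 is not > 0.5
  expect_equal(classify_regulated(list(dpsi = c(10, -10),
                                       probability = 0.5)), "ambiguous")
})

test_that("binarization keeps opposing main junctions explaining >= 50%", {
  b <- binarize_lsv(list(dpsi = c(10, -8, -2)))
  expect_true(b$retained)
  expect_equal(c(b$dpsi_main, b$dpsi_second), c(10, -8))

  expect_false(binarize_lsv(list(dpsi = c(10, -4, -3, -3)))$retained)
  expect_true(binarize_lsv(list(dpsi = c(10, -10)))$retained)
  ## same-sign second junction is rejected even if large
  expect_false(binarize_lsv(list(dpsi = c(18, 10, -8)))$retained)
  expect_error(binarize_lsv(list(dpsi = 5)), "2 junctions")
})

test_that("binarization agrees with the exhaustive oracle on random LSVs", {
  withr::with_seed(123, {
    for (i in 1:1000) {
      k <- sample(2:5, 1)
      d <- round(runif(k, -30, 30), 3)
      got <- binarize_lsv(list(dpsi = d))
      want <- binarize_oracle(d)
      expect_identical(got$retained, want$retained)
      if (got$retained) {
        expect_identical(got$dpsi_main, want$dpsi_main)
        expect_identical(got$dpsi_second, want$dpsi_second)
      }
    }
  })
})

test_that("event classification applies the junction-geometry rules", {
  cp <- cassette_pair()
  ev <- classify_event(cp$source, cp$target)
  expect_equal(ev$type, "cassette")
  expect_equal(ev$cassette_exon, cp$exon)

  ## shared donor, acceptors 50 nt apart
  a3 <- lsv_record("s", "source", dpsi = c(8, -8), probability = 0.9,
                   junctions = data.frame(start = c(100, 100),
                                          end = c(400, 450)))
  a3t <- lsv_record("t", "target", dpsi = c(8, -8), probability = 0.9,
                    junctions = data.frame(start = c(100, 100),
                                           end = c(400, 450)))
  expect_equal(classify_event(a3, a3t)$type, "alt_3ss")

  ## shared acceptor, differing donors
  a5 <- lsv_record("s", "source", dpsi = c(8, -8), probability = 0.9,
                   junctions = data.frame(start = c(100, 160),
                                          end = c(400, 400)))
  a5t <- lsv_record("t", "target", dpsi = c(8, -8), probability = 0.9,
                    junctions = data.frame(start = c(100, 160),
                                           end = c(400, 400)))
  expect_equal(classify_event(a5, a5t)$type, "alt_5ss")

  ## retained-intron junction vs spliced junction
  ir <- lsv_record("s", "source", dpsi = c(8, -8), probability = 0.9,
                   junctions = data.frame(start = c(100, 100),
                                          end = c(400, 400),
                                          ir = c(TRUE, FALSE)))
  irt <- lsv_record("t", "target", dpsi = c(8, -8), probability = 0.9,
                    junctions = data.frame(start = c(100, 100),
                                           end = c(400, 400),
                                           ir = c(FALSE, FALSE)))
  expect_equal(classify_event(ir, irt)$type, "intron_retention")

  ## unregulated input is refused
  weak <- lsv_record("s", "source", dpsi = c(1, -1), probability = 0,
                     junctions = data.frame(start = c(100, 100),
                                            end = c(400, 450)))
  expect_error(classify_event(weak, a3t), "regulated")
})

test_that("cassette sub-classification locates the variable exon", {
  cp <- cassette_pair(D = 1000, e1 = 2000, e2 = 2100, A = 3000)
  ev <- classify_event(cp$source, cp$target)
  model <- data.frame(start = c(500, 2000, 3001, 4000),
                      end = c(1000, 2100, 3500, 4500))
  expect_equal(subclassify_cassette(ev, model), "simple")

  first <- data.frame(start = c(2000, 3001, 4000),
                      end = c(2100, 3500, 4500))
  expect_equal(subclassify_cassette(ev, first), "alt_first_exon")

  last <- data.frame(start = c(500, 1500, 2000),
                     end = c(1000, 1800, 2100))
  expect_equal(subclassify_cassette(ev, last), "alt_last_exon")

  ## more than two active junctions in an LSV -> complex
  complex_src <- lsv_record("s", "source", dpsi = c(10, -6, -4),
                            probability = 0.9,
                            junctions = data.frame(
                              start = c(1000, 1000, 1000),
                              end = c(3000, 1999, 2500)))
  expect_equal(subclassify_cassette(ev, model,
                                    source_lsv = complex_src), "complex")

  ## no transcript model: first/last distinction unknown
  expect_equal(subclassify_cassette(ev), "unknown")
})

test_that("polyA-read counting is strand-aware and ignores templated A runs", {
  reg <- list(chrom = "chrT", start = 1000, end = 3000)
  rd <- simulate_reads(reg, n_pa = 5, n_plain = 7, tail_len = 8, seed = 2)
  pc <- count_pa_reads(rd, reg)
  expect_equal(pc$n_pa, 5)
  expect_equal(pc$n_total, 12)

  ## reverse-strand read with a 5' T-clip counts
  rev <- data.frame(qname = "r1", flag = 16L, rname = "chrT", pos = 1500L,
                    mapq = 60L, cigar = "8S40M",
                    seq = paste0(strrep("T", 8), strrep("G", 40)))
  expect_equal(count_pa_reads(rev, reg)$n_pa, 1)

  ## decoys: templated (aligned) A-run; short clip; low-A clip
  decoys <- data.frame(
    qname = c("d1", "d2", "d3"), flag = 0L, rname = "chrT",
    pos = c(1200L, 1300L, 1400L), mapq = 60L,
    cigar = c("50M", "46M4S", "42M8S"),
    seq = c(paste0(strrep("C", 25), strrep("A", 25)),
            paste0(strrep("C", 46), "AAAA"),
            paste0(strrep("C", 42), "AACCGGTT")))
  expect_equal(count_pa_reads(decoys, reg)$n_pa, 0)
  expect_equal(count_pa_reads(decoys, reg)$n_total, 3)

  ## shuffling rows never changes the count
  withr::with_seed(6, sh <- rd[sample.int(nrow(rd)), ])
  expect_equal(count_pa_reads(sh, reg)$n_pa, 5)

  ## log2 fold change with pseudocount; equal counts -> 0
  expect_equal(count_pa_reads(rd, reg, reference_count = 5)$log2fc, 0)

  ## reads whose 3' end lies outside the region are not attributed
  out <- data.frame(qname = "o", flag = 0L, rname = "chrT", pos = 2980L,
                    mapq = 60L, cigar = "40M8S",
                    seq = paste0(strrep("C", 40), strrep("A", 8)))
  expect_equal(count_pa_reads(out, reg)$n_total, 0)

  expect_error(count_pa_reads(rd, list(chrom = "chrT", start = 10,
                                       end = 5)), "empty region")
})
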