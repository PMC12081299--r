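# build a sparse RNA matrix whose cells have prescribed UMI totals and
# detected gene counts
rna_fixture <- function(umis, genes_detected, n_genes = 2000) {
  stopifnot(all(umis >= genes_detected))
  cols <- lapply(seq_along(umis), function(i) {
    g <- genes_detected[i]
    counts <- rep(1L, g)
    extra <- umis[i] - g
    counts[seq_len(min(g, 1))] <- counts[seq_len(min(g, 1))] + extra
    list(i = seq_len(g), x = counts)
  })
  m <- Matrix::sparseMatrix(
    i = unlist(lapply(cols, `[[`, "i")),
    j = rep(seq_along(umis), vapply(cols, function(c) length(c$i), 0L)),
    x = unlist(lapply(cols, `[[`, "x")),
    dims = c(n_genes, length(umis)),
    dimnames = list(sprintf("g%04d", seq_len(n_genes)),
                    sprintf("c%02d", seq_along(umis))))
  m
}

test_that("RNA cell filters apply inclusive ranges and a strict mito bound", {
  m <- rna_fixture(umis = c(10000, 1999, 2000, 40000, 40001, 10000, 10000,
                            15000, 5000),
                   genes_detected = c(3000, 1500, 1500, 1500, 1500, 999,
                                      1000, 10000 - 1, 1500),
                   n_genes = 12000)
  mito <- c(0.02, 0, 0, 0, 0, 0, 0, 0, 0.10)
  names(mito) <- colnames(m)
  out <- filter_rna_cells(m, mito)
  kept <- colnames(out)
  expect_true("c01" %in% kept)            # mid-range cell retained
  expect_false("c02" %in% kept)           # UMI 1,999 below the range
  expect_true("c03" %in% kept)            # UMI 2,000 inclusive
  expect_true("c04" %in% kept)            # UMI 40,000 inclusive
  expect_false("c05" %in% kept)           # UMI 40,001 above the range
  expect_false("c06" %in% kept)           # 999 genes below the range
  expect_true("c07" %in% kept)            # 1,000 genes inclusive
  expect_false("c09" %in% kept)           # mito exactly 0.10 is removed
  expect_identical(kept, intersect(colnames(m), kept))  # order preserved
  expect_error(filter_rna_cells(m, NULL), "required")
})

test_that("ATAC cell filters are inclusive on fragments, strict on mito/FRiP", {
  frags <- c(a = 50000, b = 5000, c = 4999, d = 100000, e = 100001,
             f = 50000, g = 50000, h = 50000)
  mito <- c(0.05, 0.01, 0.01, 0.01, 0.01, 0.15, 0.1499, 0.01)
  frip <- c(0.40, 0.30, 0.30, 0.30, 0.30, 0.30, 0.30, 0.25)
  kept <- filter_atac_cells(frags, mito, frip)
  expect_identical(kept, c("a", "b", "d", "g"))
  expect_identical(filter_atac_cells(numeric(0), numeric(0), numeric(0)),
                   character(0))
  expect_error(filter_atac_cells(-1, 0.1, 0.5), "negative")
})

test_that("log normalization matches the closed form and its invariances", {
  m <- Matrix::sparseMatrix(i = c(1, 2, 3), j = c(1, 1, 2),
                            x = c(100, 9900, 7),
                            dims = c(3, 2),
                            dimnames = list(letters[1:3], c("c1", "c2")))
  n <- log_normalize(m, scale_factor = 1e4)
  expect_equal(n["a", "c1"], log(101), tolerance = 1e-12)  # ln(101) ~ 4.6151
  expect_identical(n["c", "c1"], 0)                        # zeros stay zero
  # doubling all counts of a cell changes nothing
  m2 <- m; m2[, 1] <- m2[, 1] * 2
  expect_equal(as.matrix(log_normalize(m2)), as.matrix(n), tolerance = 1e-12)
  # a cell with zero total is an error naming the cell
  m3 <- m; m3[, 2] <- 0
  expect_error(log_normalize(Matrix::drop0(m3)), "c2")
})

test_that("peak merging follows the 500-bp rule and matches the closure oracle", {
  p1 <- tibble::tibble(chrom = "chr1", start = 100, end = 200)
  p2 <- tibble::tibble(chrom = "chr1", start = 650, end = 700)
  merged <- merge_peaks(list(p1, p2), max_gap = 500)
  expect_identical(nrow(merged), 1L)       # gap 450 merges
  expect_identical(c(merged$start, merged$end), c(100, 700))

  far <- merge_peaks(list(p1, tibble::tibble(chrom = "chr1", start = 702,
                                             end = 800)), max_gap = 500)
  expect_identical(nrow(far), 2L)          # gap 502 does not merge

  # gap = next_start - prev_end = 501 must NOT merge
  boundary <- merge_peaks(tibble::tibble(
    chrom = "chr1", start = c(100, 701), end = c(200, 800)), max_gap = 500)
  expect_identical(nrow(boundary), 2L)

  # chains merge transitively
  chain <- tibble::tibble(chrom = "chr1", start = c(0, 600, 1200),
                          end = c(100, 700, 1300))
  expect_identical(nrow(merge_peaks(chain, 500)), 1L)

  withr::with_seed(8, {
    for (rep in 1:10) {
      rnd <- tibble::tibble(
        chrom = sample(c("chr1", "chr2"), 40, replace = TRUE),
        start = sample(0:5000, 40))
      rnd$end <- rnd$start + sample(50:400, 40, replace = TRUE)
      got <- merge_peaks(rnd, 500)
      want <- oracle_merge(as.data.frame(rnd), 500)
      expect_equal(as.data.frame(got), want)
      # idempotence
      expect_equal(as.data.frame(merge_peaks(got, 500)), as.data.frame(got))
    }
  })
  expect_error(merge_peaks(tibble::tibble(chrom = "chr1", start = 10,
                                          end = 10)), "record 1")
})

test_that("gap of exactly 500 bp merges (boundary of the rule)", {
  m <- merge_peaks(tibble::tibble(chrom = "chr1", start = c(100, 700),
                                  end = c(200, 800)), max_gap = 500)
  expect_identical(nrow(m), 1L)
})

test_that("the Gini index matches the double-loop oracle", {
  expect_identical(gini_index(c(5, 5, 5, 5)), 0)
  expect_equal(gini_index(c(0, 0, 0, 1)), 0.75, tolerance = 1e-12)
  expect_equal(gini_index(c(1, 2, 3)), 2 / 9, tolerance = 1e-12)
  withr::with_seed(13, {
    for (rep in 1:20) {
      x <- rpois(sample(2:30, 1), 3)
      if (all(x == 0)) x[1] <- 1
      expect_equal(gini_index(x), oracle_gini(x), tolerance = 1e-12)
    }
  })
  expect_error(gini_index(c(0, 0)), "all-zero")
  expect_error(gini_index(5), "at least 2")
})

test_that("gene filtering removes patient-specific and unexpressed genes", {
  pb <- rbind(one_patient = c(50, rep(0, 21)),       # Gini 21/22 > 0.8
              uniform = rep(10, 22),
              low = rep(1, 22))
  fr <- rbind(one_patient = c(0.5, rep(0, 21)),
              uniform = rep(0.5, 22),
              low = c(0.003, rep(0.001, 21)))        # 0.3% in one patient
  res <- filter_genes(pb, fr)
  expect_false(res$keep[res$gene == "one_patient"])
  expect_true(res$keep[res$gene == "uniform"])
  expect_true(res$keep[res$gene == "low"])           # not <0.2% in ALL

  nofr <- rbind(g = rep(10, 22))
  fr2 <- rbind(g = rep(0.001, 22))                   # <0.2% everywhere
  expect_false(filter_genes(nofr, fr2)$keep)

  expect_warning(filter_genes(matrix(1:3, ncol = 1), matrix(rep(0.5, 3),
                                                            ncol = 1)),
                 "single patient")
})
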