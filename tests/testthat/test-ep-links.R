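test_that("candidate peaks use the midpoint-in-window rule inclusively", {
  promoters <- tibble::tibble(gene = "g1", chrom = "chr1", tss = 1000000,
                              strand = "+")
  peaks <- tibble::tibble(peak = c("in_edge", "out_edge", "other_chr"),
                          chrom = c("chr1", "chr1", "chr2"),
                          start = c(1499998, 1500000, 1499998),
                          end = c(1500000, 1500002, 1500000))
  got <- candidate_peaks("g1", promoters, peaks, 500000)
  expect_identical(got$peak, "in_edge")    # midpoint 1,499,999 in; 1,500,001 out
  expect_error(candidate_peaks("nope", promoters, peaks), "not found")

  # random fixture against a brute-force scan
  withr::with_seed(5, {
    pk <- tibble::tibble(peak = sprintf("p%03d", 1:300),
                         chrom = sample(c("chr1", "chr2"), 300, TRUE),
                         start = sample(0:3000000, 300))
    pk$end <- pk$start + 500
    want <- pk$peak[pk$chrom == "chr1" &
                      abs((pk$start + pk$end) / 2 - 1000000) <= 500000]
    expect_identical(candidate_peaks("g1", promoters, pk, 500000)$peak, want)
  })
})

test_that("per-gene OLS matches the normal-equations oracle", {
  withr::with_seed(17, {
    for (rep in 1:25) {
      n <- 50
      p <- sample(1:10, 1)
      X <- matrix(rnorm(n * p), n, p,
                  dimnames = list(NULL, sprintf("pk%02d", seq_len(p))))
      y <- rnorm(n)
      fit <- fit_gene_model(y, X, standardize = FALSE)
      want <- oracle_ols(y, X)
      expect_equal(fit$coefficient, unname(as.numeric(want$coef)),
                   tolerance = 1e-8)
      expect_equal(fit$std_error, unname(want$se), tolerance = 1e-8)
      expect_equal(fit$p_value, unname(as.numeric(want$p)), tolerance = 1e-8)
    }
  })
})

test_that("standardized fits recover exact relationships", {
  withr::with_seed(2, {
    x <- rnorm(20)
    fit <- fit_gene_model(x, cbind(pk = x), standardize = TRUE)
    expect_equal(fit$coefficient, 1, tolerance = 1e-10)
    expect_lt(fit$p_value, 1e-12)

    # zero-variance column is excluded with a reason
    X <- cbind(flat = rep(2, 20), ok = rnorm(20))
    fit2 <- fit_gene_model(rnorm(20), X)
    expect_identical(fit2$dropped_reason[fit2$peak == "flat"],
                     "zero variance")
    expect_true(is.na(fit2$coefficient[fit2$peak == "flat"]))

    # orthogonal standardized predictors, exact y = 0.5 x1
    x1 <- c(scale(rnorm(40)))
    x2r <- rnorm(40)
    x2 <- c(scale(residuals(lm(x2r ~ x1))))    # orthogonal to x1
    y <- 0.5 * x1
    fit3 <- fit_gene_model(y, cbind(a = x1, b = x2), standardize = FALSE)
    expect_equal(fit3$coefficient, c(0.5, 0), tolerance = 1e-8)
  })
})

test_that("BH adjustment equals step-up enumeration", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4),
               tolerance = 1e-12)
  expect_equal(bh_adjust(c(0.001, 0.02, 0.03, 0.5)),
               c(0.004, 0.04, 0.04, 0.5), tolerance = 1e-12)
  expect_identical(bh_adjust(0.37), 0.37)
  expect_identical(bh_adjust(numeric(0)), numeric(0))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")

  withr::with_seed(23, {
    for (rep in 1:50) {
      p <- runif(sample(1:40, 1))
      expect_equal(bh_adjust(p), oracle_bh(p), tolerance = 1e-12)
    }
    # monotonicity: raising any p never lowers any q
    p <- runif(20)
    q0 <- bh_adjust(p)
    i <- sample(20, 1)
    p2 <- p; p2[i] <- min(1, p2[i] + runif(1, 0, 1 - p2[i]))
    expect_true(all(bh_adjust(p2) >= q0 - 1e-12))
  })
})

test_that("link calling applies both thresholds strictly", {
  tbl <- tibble::tibble(coefficient = c(0.25, 0.15, 0.25, 0.2, 0.3),
                        q_value = c(0.005, 0.001, 0.02, 0.005, 0.0099))
  got <- call_links(tbl)
  expect_identical(got$significant, c(TRUE, FALSE, FALSE, FALSE, TRUE))
})

test_that("a planted single-gene fixture is recovered end to end", {
  withr::with_seed(31, {
    n_mc <- 80
    acc <- matrix(runif(5 * n_mc), 5, n_mc,
                  dimnames = list(sprintf("pk%d", 1:5),
                                  sprintf("mc%02d", seq_len(n_mc))))
    expr <- matrix(2 * acc["pk2", ] + rnorm(n_mc, sd = 0.2), 1, n_mc,
                   dimnames = list("g1", colnames(acc)))
    promoters <- tibble::tibble(gene = "g1", chrom = "chr1", tss = 5000,
                                strand = "+")
    peaks <- tibble::tibble(peak = rownames(acc), chrom = "chr1",
                            start = seq(1000, 9000, length.out = 5),
                            end = seq(1000, 9000, length.out = 5) + 200)
    links <- link_enhancers(expr, acc, promoters, peaks)
    expect_s3_class(links, "ep_links")
    sig <- tidy(links)[tidy(links)$significant, ]
    expect_identical(sig$peak, "pk2")
    expect_identical(glance(links)$n_significant, 1L)
  })
})

test_that("permuted expression yields almost no significant links", {
  withr::with_seed(77, {
    n_mc <- 100
    acc <- matrix(runif(40 * n_mc), 40, n_mc,
                  dimnames = list(sprintf("pk%02d", 1:40),
                                  sprintf("mc%03d", seq_len(n_mc))))
    expr <- matrix(rnorm(8 * n_mc), 8, n_mc,
                   dimnames = list(sprintf("g%d", 1:8), colnames(acc)))
    promoters <- tibble::tibble(gene = rownames(expr), chrom = "chr1",
                                tss = seq(10000, 80000, by = 10000),
                                strand = "+")
    peaks <- tibble::tibble(peak = rownames(acc), chrom = "chr1",
                            start = round(seq(5000, 85000, length.out = 40)),
                            end = round(seq(5000, 85000,
                                            length.out = 40)) + 300)
    links <- link_enhancers(expr, acc, promoters, peaks)
    expect_lte(mean(links$significant), attr(links, "thresholds")$q_max)
  })
})

test_that("under-determined genes are skipped with a warning", {
  acc <- matrix(runif(30 * 10), 30, 10,
                dimnames = list(sprintf("pk%02d", 1:30),
                                sprintf("mc%02d", 1:10)))
  expr <- matrix(rnorm(10), 1, 10, dimnames = list("g1", colnames(acc)))
  promoters <- tibble::tibble(gene = "g1", chrom = "chr1", tss = 500,
                              strand = "+")
  peaks <- tibble::tibble(peak = rownames(acc), chrom = "chr1",
                          start = seq_len(30) * 10, end = seq_len(30) * 10 + 5)
  expect_warning(links <- link_enhancers(expr, acc, promoters, peaks),
                 "under-determined")
  expect_identical(nrow(links), 0L)
  expect_identical(attr(links, "skipped")$gene, "g1")
})
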