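# enumerable fixture: 2 TFs, 3 target genes, 4 peaks, one state "S"
trn_fixture <- function(tf2_expr = 0.5) {
  links <- tibble::tibble(
    gene = c("g1", "g1", "g2", "g3", "g2"),
    peak = c("pk1", "pk2", "pk3", "pk4", "pk1"),
    coefficient = c(0.5, 0.3, 0.4, 0.25, 0.1),
    q_value = c(1e-4, 1e-4, 1e-4, 1e-4, 0.5),
    significant = c(TRUE, TRUE, TRUE, TRUE, FALSE))
  hits <- matrix(c(1, 1, 0, 1,    # tf1 at pk1, pk2, pk4
                   0, 1, 1, 0),   # tf2 at pk2, pk3
                 nrow = 4,
                 dimnames = list(c("pk1", "pk2", "pk3", "pk4"),
                                 c("tf1", "tf2")))
  de <- tibble::tibble(
    gene = c("g1", "g2", "g3", "tf1"), state = "S",
    log_fc = c(1, 0.8, 0.6, 0.5), q_value = c(1e-3, 1e-3, 1e-3, 1e-3))
  da <- tibble::tibble(
    peak = c("pk1", "pk2", "pk3", "pk4"), state = "S",
    log_fc = c(2, 1.5, 1, 1), q_value = c(1e-3, 1e-3, 1e-3, 0.5))
  motif <- tibble::tibble(
    motif = c("tf1", "tf2"), state = "S",
    activity_diff = c(1.2, 0.9), q_value = c(1e-3, 1e-3))
  expr_frac <- c(tf1 = 0.5, tf2 = tf2_expr, g1 = 0.9, g2 = 0.9, g3 = 0.9)
  acc_frac <- c(pk1 = 0.4, pk2 = 0.5, pk3 = 0.6, pk4 = 0.20)
  list(links = links, hits = hits, de = de, da = da, motif = motif,
       expr_frac = expr_frac, acc_frac = acc_frac)
}

test_that("network assembly equals by-hand rule enumeration", {
  fx <- trn_fixture()
  nw <- assemble_network(fx$links, fx$hits, fx$de, fx$da, fx$motif,
                         fx$expr_frac, fx$acc_frac, state = "S")
  # pk4 is not DA, so g3 has no surviving link; the non-significant
  # (g2, pk1) link never enters
  want <- tibble::tibble(
    tf = c("tf1", "tf1", "tf2", "tf2"),
    target = c("g1", "g1", "g1", "g2"),
    peak = c("pk1", "pk2", "pk2", "pk3"),
    coefficient = c(0.5, 0.3, 0.3, 0.4),
    accessible_fraction = c(0.4, 0.5, 0.5, 0.6),
    weight = c(0.2, 0.15, 0.15, 0.24))
  got <- dplyr::arrange(nw$edges, tf, target, peak)
  expect_equal(as.data.frame(got), as.data.frame(want), tolerance = 1e-12)
  expect_setequal(nw$tf_nodes$tf, c("tf1", "tf2"))
  expect_identical(nw$tf_nodes$included_by[nw$tf_nodes$tf == "tf1"],
                   "DE+motif_activity")
  expect_setequal(nw$target_nodes$gene, c("g1", "g2"))
  validate_trn(nw, fx$links, fx$hits)
})

test_that("a TF expressed in under 20% of state cells is excluded", {
  fx <- trn_fixture(tf2_expr = 0.19)
  nw <- assemble_network(fx$links, fx$hits, fx$de, fx$da, fx$motif,
                         fx$expr_frac, fx$acc_frac, state = "S")
  expect_false("tf2" %in% nw$edges$tf)
  # exactly 20% is included ("at least 20%")
  fx20 <- trn_fixture(tf2_expr = 0.20)
  nw20 <- assemble_network(fx20$links, fx20$hits, fx20$de, fx20$da,
                           fx20$motif, fx20$expr_frac, fx20$acc_frac,
                           state = "S")
  expect_true("tf2" %in% nw20$edges$tf)
})

test_that("sparse-state mode replaces the DA gate by a strict 20% rule", {
  fx <- trn_fixture()
  nw <- assemble_network(fx$links, fx$hits, fx$de, da_table = NULL,
                         fx$motif, fx$expr_frac, fx$acc_frac, state = "S",
                         sparse_state_mode = TRUE)
  # pk4 has accessible fraction exactly 0.20: strictly-greater rule fails
  expect_false("pk4" %in% nw$edges$peak)
  expect_true(all(c("pk1", "pk2", "pk3") %in% nw$edges$peak))
  # but without sparse mode the DA table is required
  expect_error(assemble_network(fx$links, fx$hits, fx$de, NULL, fx$motif,
                                fx$expr_frac, fx$acc_frac, state = "S"),
               "da_table")
})

test_that("no significant links yields an empty network", {
  fx <- trn_fixture()
  fx$links$significant <- FALSE
  nw <- assemble_network(fx$links, fx$hits, fx$de, fx$da, fx$motif,
                         fx$expr_frac, fx$acc_frac, state = "S")
  expect_identical(nrow(nw$edges), 0L)
  expect_identical(nrow(nw$tf_nodes), 0L)
  validate_trn(nw, fx$links, fx$hits)
})

test_that("removing a TF's motif hits removes exactly its edges", {
  fx <- trn_fixture()
  full <- assemble_network(fx$links, fx$hits, fx$de, fx$da, fx$motif,
                           fx$expr_frac, fx$acc_frac, state = "S")
  hits2 <- fx$hits; hits2[, "tf2"] <- 0
  fx$motif <- fx$motif[fx$motif$motif != "tf2", ]   # no hits -> no motif row
  cut <- assemble_network(fx$links, hits2, fx$de, fx$da, fx$motif,
                          fx$expr_frac, fx$acc_frac, state = "S")
  expect_identical(cut$edges, full$edges[full$edges$tf != "tf2", ])
})

test_that("edge weights are products and validated", {
  expect_identical(edge_weight(0.5, 0.4), 0.2)
  expect_identical(edge_weight(0.7, 0), 0)
  expect_equal(edge_weight(c(0.2, 0.4), c(0.5, 0.25)), c(0.1, 0.1))
  expect_error(edge_weight(0.5, 1.2), "\\[0, 1\\]")
})

test_that("top regulators rank by target coverage with lexicographic ties", {
  fx <- trn_fixture()
  nw <- assemble_network(fx$links, fx$hits, fx$de, fx$da, fx$motif,
                         fx$expr_frac, fx$acc_frac, state = "S")
  # tf1 covers g1 only (1/2); tf2 covers g1 and g2 (2/2)
  top <- top_regulators(nw)
  expect_identical(top$tf, c("tf2", "tf1"))
  expect_equal(top$fraction_targets, c(1, 0.5))

  # tie: restrict to a single shared target
  nw$edges <- nw$edges[nw$edges$target == "g1", ]
  nw$target_nodes <- nw$target_nodes[nw$target_nodes$gene == "g1", ]
  tie <- top_regulators(nw)
  expect_identical(tie$tf, c("tf1", "tf2"))  # equal coverage, name order
  empty <- structure(list(state = "S",
                          tf_nodes = nw$tf_nodes[0, ],
                          target_nodes = nw$target_nodes[0, ],
                          edges = nw$edges[0, ]), class = "trn_network")
  expect_identical(nrow(top_regulators(empty)), 0L)
})

test_that("DX/PTX direction reflects planted shifts and label swaps", {
  norm <- rbind(up = c(1, 1, 2, 2), flat = c(1, 1, 1, 1))
  colnames(norm) <- sprintf("c%d", 1:4)
  tp <- c(c1 = "DX", c2 = "DX", c3 = "PTX", c4 = "PTX")
  got <- dx_ptx_direction(norm, tp)
  expect_identical(got$direction, c("up", "unchanged"))
  # swapping the labels flips the sign
  tp_sw <- setNames(c("PTX", "PTX", "DX", "DX"), names(tp))
  got_sw <- dx_ptx_direction(norm, tp_sw)
  expect_identical(got_sw$direction, c("down", "unchanged"))
  expect_equal(got_sw$diff, -got$diff)
  # a missing timepoint degrades to 'unchanged' with a warning
  expect_warning(
    all_dx <- dx_ptx_direction(norm, setNames(rep("DX", 4), names(tp))),
    "absent")
  expect_true(all(all_dx$direction == "unchanged"))
})
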