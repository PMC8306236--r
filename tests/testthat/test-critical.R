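test_that("the concentration filter applies strict per-target thresholds", {
  comp <- validate_compound_table(rbind(
    make_compounds("m10", "metabolite", "UNKNOWN", fc_max = 10),
    make_compounds("m51", "metabolite", "UNKNOWN", fc_max = 5.1),
    make_compounds("m3", "metabolite", "UNKNOWN", fc_max = 3),
    make_compounds("p1", "prototype", "RA", fc_max = 1.1, base = 1.1)))
  ctis <- data.frame(
    compound_id = c("m10", "m51", "m3", "p1", "m3"),
    target_gene = c("PPARG", "SERPINE1", "PPARD", "PPARG", "CDK1"),
    origin = "predicted", stringsAsFactors = FALSE)
  out <- concentration_filter(ctis, comp)
  key <- paste(out$compound_id, out$target_gene)
  expect_false("m10 PPARG" %in% key)      # 10 is not > 10
  expect_true("m51 SERPINE1" %in% key)    # 5.1 > 5
  expect_false("m3 PPARD" %in% key)
  expect_true("p1 PPARG" %in% key)        # prototypes pass
  expect_true("m3 CDK1" %in% key)         # unthresholded target passes

  # contraction and idempotence
  out2 <- concentration_filter(out, comp)
  expect_equal(out2[, names(out)], out)
  expect_lte(nrow(out), nrow(ctis))
})

test_that("the concentration filter matches a rule-by-rule oracle", {
  withr::with_seed(43, {
    ids <- sprintf("c%02d", 1:25)
    comp <- make_compounds(
      ids,
      compound_class = sample(c("prototype", "metabolite"), 25,
                              replace = TRUE),
      herb_origin = "UNKNOWN",
      fc_max = stats::runif(25, 2, 20))
    comp$herb_origin[comp$compound_class == "prototype"] <- "RA"
    comp <- validate_compound_table(comp)
    ctis <- data.frame(
      compound_id = sample(ids, 50, replace = TRUE),
      target_gene = sample(c("PPARG", "PTGS2", "PPARD", "SERPINE1",
                             "TP53", "CDK1"), 50, replace = TRUE),
      origin = "predicted", stringsAsFactors = FALSE)
  })
  thr <- c(PPARG = 10, PTGS2 = 10, PPARD = 5, SERPINE1 = 5)
  out <- concentration_filter(ctis, comp, thr)
  for (i in seq_len(nrow(ctis))) {
    cls <- comp$compound_class[comp$compound_id == ctis$compound_id[i]]
    fc <- comp$fc_max[comp$compound_id == ctis$compound_id[i]]
    t <- thr[ctis$target_gene[i]]
    should_keep <- cls == "prototype" || is.na(t) || fc > t
    expect_equal(paste(ctis$compound_id[i], ctis$target_gene[i]) %in%
                   paste(out$compound_id, out$target_gene),
                 unname(should_keep))
  }
})

test_that("docking-score median split follows the printed convention", {
  d3 <- data.frame(compound_id = c("a", "b", "c"),
                   target_gene = "T", gscore = c(-8, -6, -4))
  s <- gscore_median_split(d3)
  expect_equal(attr(s, "median"), -6)
  expect_equal(s$strong, c(TRUE, FALSE, FALSE))
  s_alt <- gscore_median_split(d3, rule = "above_median")
  expect_equal(s_alt$strong, c(FALSE, FALSE, TRUE))

  # a single record equals its own median, hence weak
  s1 <- gscore_median_split(d3[1, ])
  expect_false(s1$strong)
  expect_error(gscore_median_split(d3[0, ]), "empty")

  # the seven printed scores: median -7.534 belongs to MOL43-PPARG,
  # the minimum -8.29 to MOL10-PTGS2
  tab <- table1_dock()
  split <- gscore_median_split(tab)
  expect_equal(attr(split, "median"), -7.534)
  med_row <- split[split$gscore == attr(split, "median"), ]
  expect_equal(med_row$compound_id, "MOL43")
  expect_equal(med_row$target_gene, "PPARG")
  min_row <- split[which.min(split$gscore), ]
  expect_equal(min_row$compound_id, "MOL10")
  expect_equal(min_row$target_gene, "PTGS2")
})

test_that("the known channel keeps the largest fold-change interaction", {
  comp <- validate_compound_table(make_compounds(c("a", "b"),
                                                 fc_max = c(3, 7)))
  known <- data.frame(compound_id = c("a", "b"), target_gene = "T1",
                      stringsAsFactors = FALSE)
  crit <- select_critical(known, NULL, NULL, comp)
  expect_equal(nrow(crit), 1)
  expect_equal(crit$compound_id, "b")
  expect_equal(crit$origin, "known")
})

test_that("the predicted channel resolves score/fold-change conflicts by policy", {
  comp <- validate_compound_table(make_compounds(c("x", "y", "z"),
                                                 fc_max = c(100, 50, 20)))
  # x: best fold change, worst score; z: best score, worst fold change;
  # y: dominated by neither order but Pareto-dominated by nobody either
  dock <- data.frame(compound_id = c("x", "y", "z"), target_gene = "T1",
                     gscore = c(-5, -6, -7), stringsAsFactors = FALSE)
  pred <- dock[, 1:2]
  pred$origin <- "predicted"

  crit <- select_critical(NULL, pred, dock, comp)  # pareto, score first
  expect_equal(crit$compound_id, "z")
  expect_equal(select_critical(NULL, pred, dock, comp,
                               tie_policy = "fcmax_only")$compound_id, "x")
  expect_equal(select_critical(NULL, pred, dock, comp,
                               tie_policy = "gscore_only")$compound_id, "z")

  # dominated candidates never win under the default policy: enumerate
  # every ordering of three candidates
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                c(3, 1, 2), c(3, 2, 1))
  for (pg in perms) for (pf in perms) {
    comp3 <- validate_compound_table(make_compounds(
      c("a", "b", "c"), fc_max = c(10, 20, 30)[pf]))
    dock3 <- data.frame(compound_id = c("a", "b", "c"), target_gene = "T",
                        gscore = c(-9, -8, -7)[pg], stringsAsFactors = FALSE)
    pred3 <- dock3[, 1:2]
    sel <- select_critical(NULL, pred3, dock3, comp3)
    fc <- comp3$fc_max[match(dock3$compound_id, comp3$compound_id)]
    keep <- herbnet:::pareto_front(dock3$gscore, fc)
    front <- dock3$compound_id[keep]
    winner <- front[order(dock3$gscore[keep], -fc[keep], front)][1]
    expect_equal(sel$compound_id, winner)
  }

  # pareto_all keeps every non-dominated candidate: both PTGS2 binders
  # (one with the lower score, one with the higher fold change) survive
  comp2 <- validate_compound_table(critical_compounds())
  dock2 <- table1_dock()
  pred2 <- dock2[dock2$target_gene == "PTGS2", 1:2]
  both <- select_critical(NULL, pred2, dock2, comp2,
                          tie_policy = "pareto_all")
  expect_setequal(both$compound_id, c("MOL43", "MOL10"))
  one <- select_critical(NULL, pred2, dock2, comp2)
  expect_equal(one$compound_id, "MOL10")  # lower score wins by default

  # a single predicted candidate is always kept
  expect_equal(nrow(select_critical(NULL, pred[1, ], dock, comp)), 1)
  # a predicted candidate without a docking score is an error
  expect_error(select_critical(NULL, pred, dock[-2, ], comp),
               "without docking score")
})

test_that("each target contributes at most one interaction per channel", {
  withr::with_seed(47, {
    comp <- validate_compound_table(make_compounds(
      sprintf("c%02d", 1:12), fc_max = stats::runif(12, 2, 40)))
    known <- data.frame(
      compound_id = sample(comp$compound_id, 10, replace = TRUE),
      target_gene = sample(c("T1", "T2", "T3"), 10, replace = TRUE),
      stringsAsFactors = FALSE)
    pred <- unique(data.frame(
      compound_id = sample(comp$compound_id, 10, replace = TRUE),
      target_gene = sample(c("T1", "T2", "T4"), 10, replace = TRUE),
      stringsAsFactors = FALSE))
    dock <- pred
    dock$gscore <- stats::rnorm(nrow(dock), -6)
  })
  crit <- select_critical(known, pred, dock, comp)
  per <- table(crit$target_gene, crit$origin)
  expect_true(all(per <= 1))
})

test_that("the printed critical interactions build the reported network", {
  crit <- critical_worked_example()
  comp <- validate_compound_table(critical_compounds())
  g <- build_critical_network(crit, comp)
  expect_equal(sum(igraph::V(g)$kind == "compound"), 8)
  expect_equal(sum(igraph::V(g)$kind == "target"), 8)
  expect_equal(igraph::ecount(g), 10)
  expect_equal(sum(igraph::E(g)$origin == "predicted"), 7)
  expect_equal(sum(igraph::E(g)$origin == "known"), 3)
  expect_equal(igraph::degree(g, "MOL43"), c(MOL43 = 3))
  expect_setequal(
    igraph::V(g)$name[igraph::neighbors(g, "MOL43")],
    c("PTGS2", "PPARG", "SERPINE1"))
  expect_true(igraph::is_bipartite(g))
  # every predicted edge carries its docking score
  expect_true(all(!is.na(igraph::E(g)$gscore[igraph::E(g)$origin ==
                                               "predicted"])))

  # a single interaction gives a 2-node, 1-edge graph
  g1 <- build_critical_network(crit[1, ], comp)
  expect_equal(igraph::vcount(g1), 2)
  expect_equal(igraph::ecount(g1), 1)

  # node counts equal the unique-endpoint tally on random lists
  withr::with_seed(53, {
    for (i in 1:10) {
      sub <- crit[sample(nrow(crit), sample(2:10, 1)), ]
      gg <- build_critical_network(sub, comp)
      expect_equal(igraph::vcount(gg),
                   length(unique(sub$compound_id)) +
                     length(unique(sub$target_gene)))
    }
  })
})

test_that("cross-docking consistency flags columnwise minima", {
  sel <- data.frame(compound_id = c("a", "b"), target_gene = c("T1", "T2"),
                    stringsAsFactors = FALSE)
  dock <- data.frame(
    compound_id = c("a", "b", "a", "b"),
    target_gene = c("T1", "T1", "T2", "T2"),
    gscore = c(-9, -5, -4, -8), stringsAsFactors = FALSE)
  rep <- cross_dock_consistency(dock, sel)
  expect_true(all(rep$consistent))
  expect_equal(attr(rep, "fraction"), 1)

  dock$gscore[2] <- -10  # one inversion at T1
  rep2 <- cross_dock_consistency(dock, sel)
  expect_equal(attr(rep2, "fraction"), 0.5)

  withr::with_seed(59, {
    for (i in 1:10) {
      m <- matrix(stats::rnorm(12, -6), 3, 4,
                  dimnames = list(c("a", "b", "c"), paste0("T", 1:4)))
      long <- data.frame(compound_id = rep(rownames(m), 4),
                         target_gene = rep(colnames(m), each = 3),
                         gscore = as.vector(m), stringsAsFactors = FALSE)
      sel <- data.frame(compound_id = sample(rownames(m), 4,
                                             replace = TRUE),
                        target_gene = colnames(m), stringsAsFactors = FALSE)
      rep3 <- cross_dock_consistency(long, sel)
      oracle <- vapply(seq_len(4), function(j) {
        m[sel$compound_id[j], j] == min(m[, j])
      }, logical(1))
      expect_equal(rep3$consistent, oracle)
    }
  })
})
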