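test_that("activity filtering keeps values at or below the cutoff", {
  act <- data.frame(
    compound_id = c("A", "A", "B"),
    target_gene = c("TP53", "TP53", "AR"),
    measure_kind = c("IC50", "Ki", "Ki"),
    value_uM = c(10, 0.2, 50),
    stringsAsFactors = FALSE)
  known <- filter_known_ctis(act, 10)
  expect_equal(nrow(known), 1)  # IC50 = 10 kept, duplicate collapsed
  expect_equal(known$compound_id, "A")
  expect_false("AR" %in% known$target_gene)  # Ki = 50 dropped
  expect_error(filter_known_ctis(transform(act, value_uM = c(1, -1, 2)), 10),
               "non-positive")
})

test_that("duplicate activity records collapse to unique pairs", {
  withr::with_seed(5, {
    act <- data.frame(
      compound_id = sample(LETTERS[1:4], 20, replace = TRUE),
      target_gene = sample(c("TP53", "AR", "MMP9"), 20, replace = TRUE),
      measure_kind = "IC50",
      value_uM = stats::runif(20, 0.1, 20),
      stringsAsFactors = FALSE)
  })
  known <- filter_known_ctis(act, 10)
  oracle <- unique(paste(act$compound_id, act$target_gene)[act$value_uM <= 10])
  expect_equal(nrow(known), length(oracle))
  expect_setequal(paste(known$compound_id, known$target_gene), oracle)
})

test_that("SDT network construction satisfies the layer invariants", {
  ctis <- data.frame(compound_id = c("d1", "d2", "d3"),
                     target_gene = c("T1", "T2", "T3"),
                     stringsAsFactors = FALSE)
  fp <- list(d1 = c("s1", "s2"), d2 = c("s2", "s3"), d3 = c("s3", "s4"))
  net <- build_sdt_network(ctis, fp)
  expect_equal(length(net$drugs) + length(net$targets) +
                 length(net$substructures), 10)

  # handshake: row degree sums equal twice the edge count per layer
  adj <- net$adjacency
  n_dt <- nrow(net$known)
  n_ds <- sum(lengths(fp))
  expect_equal(sum(adj) / 2, n_dt + n_ds)
  drug_rows <- paste0("d:", net$drugs)
  expect_equal(sum(Matrix::rowSums(adj[drug_rows, ])), n_dt + n_ds)

  # no edges inside the target or substructure layers
  t_rows <- paste0("t:", net$targets)
  s_rows <- paste0("s:", net$substructures)
  expect_equal(sum(adj[t_rows, t_rows]), 0)
  expect_equal(sum(adj[s_rows, s_rows]), 0)
  expect_equal(sum(adj[s_rows, t_rows]), 0)

  expect_error(build_sdt_network(ctis[0, ], fp), "cannot build")

  # a drug sharing no substructure stays connected via its own targets
  fp2 <- c(fp, list(d4 = "s99"))
  ctis2 <- rbind(ctis, data.frame(compound_id = "d4", target_gene = "T1"))
  net2 <- build_sdt_network(ctis2, fp2)
  expect_gt(sum(net2$adjacency["d:d4", ]), 0)
})

test_that("diffusion matches an independent dense matrix-power oracle", {
  withr::with_seed(99, {
    for (rep in 1:10) {
      n_d <- sample(3:5, 1); n_t <- sample(3:6, 1); n_s <- sample(2:5, 1)
      drugs <- paste0("d", seq_len(n_d))
      targets <- paste0("T", seq_len(n_t))
      subs <- paste0("s", seq_len(n_s))
      ctis <- unique(data.frame(
        compound_id = sample(drugs, 2 * n_d, replace = TRUE),
        target_gene = sample(targets, 2 * n_d, replace = TRUE),
        stringsAsFactors = FALSE))
      fp <- lapply(stats::setNames(drugs, drugs),
                   function(d) sample(subs, sample(1:n_s, 1)))
      net <- build_sdt_network(ctis, fp)
      rounds <- sample(1:3, 1)
      res <- predict_targets(net, top_k = 1000, rounds = rounds)

      # dense oracle built from first principles
      nodes <- c(paste0("d:", net$drugs), paste0("t:", net$targets),
                 paste0("s:", net$substructures))
      A <- matrix(0, length(nodes), length(nodes),
                  dimnames = list(nodes, nodes))
      for (i in seq_len(nrow(net$known))) {
        a <- paste0("d:", net$known$compound_id[i])
        b <- paste0("t:", net$known$target_gene[i])
        A[a, b] <- A[b, a] <- 1
      }
      for (d in names(fp)) for (s in fp[[d]]) {
        A[paste0("d:", d), paste0("s:", s)] <- 1
        A[paste0("s:", s), paste0("d:", d)] <- 1
      }
      Tm <- sweep(A, 2, colSums(A), "/")
      for (d in net$drugs) {
        f <- as.numeric(nodes == paste0("d:", d))
        for (s in seq_len(2 * rounds + 1)) f <- as.numeric(Tm %*% f)
        names(f) <- nodes
        novel <- setdiff(net$targets, known_targets <-
                           net$known$target_gene[net$known$compound_id == d])
        sc <- if (length(novel) > 0)
          stats::setNames(f[paste0("t:", novel)], novel)
        else stats::setNames(numeric(0), character(0))
        sc <- sc[sc > 0]
        sc <- sc[order(-sc, names(sc))]
        got <- res$predictions[res$predictions$compound_id == d, ]
        expect_equal(got$target_gene, as.character(names(sc)))
        expect_equal(got$score, as.numeric(unname(sc)), tolerance = 1e-12)
      }
    }
  })
})

test_that("diffusion conserves total resource and caps the list at top_k", {
  withr::with_seed(3, {
    ctis <- unique(data.frame(
      compound_id = sample(paste0("d", 1:6), 15, replace = TRUE),
      target_gene = sample(paste0("T", 1:25), 15, replace = TRUE),
      stringsAsFactors = FALSE))
    fp <- lapply(stats::setNames(paste0("d", 1:6), paste0("d", 1:6)),
                 function(d) sample(paste0("s", 1:8), 3))
  })
  net <- build_sdt_network(ctis, fp)
  res <- predict_targets(net, top_k = 20)
  expect_true(all(table(res$predictions$compound_id) <= 20))
  # scores are non-increasing down each ranked list
  for (d in unique(res$predictions$compound_id)) {
    s <- res$predictions$score[res$predictions$compound_id == d]
    expect_true(all(diff(s) <= 1e-12))
  }
  # conservation: full resource vector sums to 1 per query
  adj <- net$adjacency
  tr <- herbnet:::sdt_transition(adj, 0)
  f <- as.numeric(rownames(adj) == paste0("d:", net$drugs[1]))
  for (s in 1:5) {
    f <- as.numeric(tr %*% f)
    expect_equal(sum(f), 1, tolerance = 1e-9)
  }
})

test_that("mirror-image drugs receive mirrored scores", {
  ctis <- data.frame(compound_id = c("d1", "d2"),
                     target_gene = c("T1", "T2"),
                     stringsAsFactors = FALSE)
  fp <- list(d1 = "s1", d2 = "s2")
  net <- build_sdt_network(ctis, fp)
  res <- predict_targets(net, top_k = 10)
  s12 <- res$predictions$score[res$predictions$compound_id == "d1" &
                                 res$predictions$target_gene == "T2"]
  s21 <- res$predictions$score[res$predictions$compound_id == "d2" &
                                 res$predictions$target_gene == "T1"]
  expect_equal(s12, s21)
})

test_that("ranked lists are invariant to input row order", {
  withr::with_seed(21, {
    ctis <- unique(data.frame(
      compound_id = sample(paste0("d", 1:5), 12, replace = TRUE),
      target_gene = sample(paste0("T", 1:10), 12, replace = TRUE),
      stringsAsFactors = FALSE))
    fp <- lapply(stats::setNames(paste0("d", 1:5), paste0("d", 1:5)),
                 function(d) sample(paste0("s", 1:6), 2))
    perm <- sample(nrow(ctis))
  })
  r1 <- predict_targets(build_sdt_network(ctis, fp))
  r2 <- predict_targets(build_sdt_network(ctis[perm, ], fp[c(3, 1, 5, 2, 4)]))
  expect_equal(r1$predictions, r2$predictions)
})

test_that("a fingerprint cloned from a known binder recovers its target", {
  hits <- 0L
  for (rep in 1:100) {
    withr::with_seed(3000 + rep, {
      drugs <- paste0("d", 1:10)
      targets <- paste0("T", 1:8)
      subs <- paste0("s", 1:20)
      ctis <- unique(data.frame(
        compound_id = sample(drugs, 25, replace = TRUE),
        target_gene = sample(targets, 25, replace = TRUE),
        stringsAsFactors = FALSE))
      fp <- lapply(stats::setNames(drugs, drugs),
                   function(d) sample(subs, 5))
      donor <- sample(drugs, 1)
      fp$query <- fp[[donor]]
      donor_targets <- ctis$target_gene[ctis$compound_id == donor]
    })
    net <- suppressWarnings(build_sdt_network(ctis, fp))
    res <- predict_targets(net, "query", top_k = 5)
    top5 <- res$predictions$target_gene
    if (any(donor_targets %in% top5)) hits <- hits + 1L
  }
  expect_gte(hits, 90)
})

test_that("merging known and predicted interactions is a keyed union", {
  known <- data.frame(compound_id = paste0("c", 1:5),
                      target_gene = paste0("T", 1:5),
                      stringsAsFactors = FALSE)
  pred <- data.frame(compound_id = paste0("c", 6:10),
                     target_gene = paste0("T", 6:10),
                     score = stats::runif(5), stringsAsFactors = FALSE)
  m <- merge_cti(known, pred)
  expect_equal(nrow(m), 10)

  # a pair in both keeps origin known
  pred2 <- rbind(pred, data.frame(compound_id = "c1", target_gene = "T1",
                                  score = 0.9))
  m2 <- merge_cti(known, pred2)
  expect_equal(nrow(m2), 10)
  expect_equal(m2$origin[m2$compound_id == "c1"], "known")

  # inclusion-exclusion on random overlaps
  withr::with_seed(17, {
    k <- unique(data.frame(
      compound_id = sample(letters[1:6], 20, replace = TRUE),
      target_gene = sample(paste0("T", 1:6), 20, replace = TRUE),
      stringsAsFactors = FALSE))
    p <- unique(data.frame(
      compound_id = sample(letters[1:6], 20, replace = TRUE),
      target_gene = sample(paste0("T", 1:6), 20, replace = TRUE),
      stringsAsFactors = FALSE))
    p$score <- stats::runif(nrow(p))
  })
  m3 <- merge_cti(k, p)
  inter <- length(intersect(paste(k$compound_id, k$target_gene),
                            paste(p$compound_id, p$target_gene)))
  expect_equal(nrow(m3), nrow(k) + nrow(p) - inter)
})
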