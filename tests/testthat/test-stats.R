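make_records <- function(n_correct, n_total, modality = "DIHM",
                         evaluator = "expert1") {
  cls <- pollen_classes()
  true <- rep(cls, length.out = n_total)
  assigned <- true
  if (n_correct < n_total) {
    flip <- (n_correct + 1):n_total
    assigned[flip] <- cls[(match(true[flip], cls)) %% 6 + 1]
  }
  data.frame(image_id = sprintf("img%03d", seq_len(n_total)),
             modality = modality, evaluator = evaluator,
             true_species = true, assigned_species = assigned,
             stringsAsFactors = FALSE)
}

test_that("accuracy rounds half-up to one decimal like the study tables", {
  expect_equal(accuracy_percent(make_records(47, 48)), 97.9)
  expect_equal(accuracy_percent(make_records(45, 48)), 93.8)  # 93.75 -> 93.8
  expect_equal(accuracy_percent(make_records(48, 48)), 100.0)
  expect_error(accuracy_percent(make_records(1, 1)[0, ]), "empty")
})

test_that("pooled accuracy pools counts, not rounded percentages", {
  d1 <- make_records(47, 48, evaluator = "expert1")
  d2 <- make_records(45, 48, evaluator = "expert2")
  expect_equal(pooled_accuracy(d1, d2), 95.8)  # 92/96, not (97.9+93.8)/2
  o1 <- make_records(46, 48, "optical", "expert1")
  o2 <- make_records(47, 48, "optical", "expert2")
  expect_equal(pooled_accuracy(o1, o2), 96.9)  # 93/96
  expect_equal(pooled_accuracy(list(d1, d2)), 95.8)
  expect_equal(pooled_accuracy(d1, d1), accuracy_percent(d1))
})

test_that("confusion matrices count and normalise by true class", {
  rec <- pollen_study_records()
  cm <- build_confusion(rec[rec$modality == "DIHM", ], normalise = TRUE)
  expect_equal(sum(cm$counts), 96L)
  expect_true(all(rowSums(cm$counts) == 16L))  # 16 evaluations per class
  expect_equal(unname(rowSums(cm$proportions)), rep(1, 6))
  expect_equal(cm$counts["silver_birch", "hazel"], 2L)
  expect_length(cm$empty_classes, 0)

  allc <- make_records(12, 12)
  cmd <- build_confusion(allc, normalise = TRUE)
  expect_equal(unname(diag(cmd$proportions)), rep(1, 6))

  bad <- allc
  bad$assigned_species[1] <- "sunflower"
  expect_error(build_confusion(bad), "unknown label")
})

test_that("per-class F1 follows the confusion-matrix definition", {
  # perfect class: no false positives, no false negatives
  cm <- build_confusion(make_records(12, 12))
  expect_equal(as.numeric(per_class_f1(cm)), rep(1.000, 6))

  # hand-checkable counts: TP=28, FP=3, FN=4 -> 56/63 -> 0.889
  counts <- diag(c(32L, 32L, 28L, 30L, 31L, 32L))
  counts[4, 3] <- 2L; counts[5, 3] <- 1L   # alder/olive read as birch
  counts[3, 6] <- 2L; counts[3, 4] <- 2L   # birch read as hazel/alder
  dimnames(counts) <- list(pollen_classes(), pollen_classes())
  cm <- structure(list(classes = pollen_classes(), counts = counts),
                  class = "confusion_matrix")
  f1 <- per_class_f1(cm)
  expect_equal(unname(f1["silver_birch"]), 0.889)
  expect_equal(unname(f1["common_alder"]), 0.938)
  expect_equal(unname(f1["olive_tree"]), 0.984)
  expect_equal(unname(f1["hazel"]), 0.970)

  # empty class scores 0 and is flagged
  counts0 <- counts; counts0[1, ] <- 0L; counts0[, 1] <- 0L
  cm0 <- structure(list(classes = pollen_classes(), counts = counts0),
                   class = "confusion_matrix")
  f10 <- per_class_f1(cm0)
  expect_equal(unname(f10["timothy_grass"]), 0)
  expect_equal(attr(f10, "empty_classes"), "timothy_grass")
})

test_that("micro-averaged F1 equals overall accuracy for single-label records", {
  rec <- pollen_study_records()
  cm <- build_confusion(rec)
  tp <- sum(diag(cm$counts))
  fp <- sum(colSums(cm$counts) - diag(cm$counts))
  fn <- sum(rowSums(cm$counts) - diag(cm$counts))
  micro_f1 <- 2 * tp / (2 * tp + fp + fn)
  expect_equal(micro_f1, tp / sum(cm$counts))
  expect_equal(holopollen:::round_half_up(100 * micro_f1, 1),
               accuracy_percent(rec))
})

test_that("Cohen's kappa matches its defining identities", {
  expect_equal(cohen_kappa(c("a", "b", "c"), c("a", "b", "c"))$kappa, 1.0)
  r <- cohen_kappa(c("x", "x", "y", "y"), c("x", "y", "x", "y"))
  expect_equal(r$observed_agreement, 0.5)
  expect_equal(r$expected_agreement, 0.5)
  expect_equal(r$kappa, 0.0)
  r2 <- cohen_kappa(c("x", "x", "x", "y"), c("x", "x", "y", "y"))
  expect_equal(r2$kappa, 0.5)  # p_o = 0.75, p_e = 0.5

  # symmetry, range, and alignment by image_id
  set.seed(31)
  a <- sample(pollen_classes(), 40, replace = TRUE)
  b <- sample(pollen_classes(), 40, replace = TRUE)
  expect_equal(cohen_kappa(a, b)$kappa, cohen_kappa(b, a)$kappa)
  expect_gte(cohen_kappa(a, b)$kappa, -1)
  expect_lte(cohen_kappa(a, b)$kappa, 1)

  ra <- data.frame(image_id = sprintf("i%02d", 1:40), modality = "DIHM",
                   evaluator = "e1", assigned_species = a)
  rb <- data.frame(image_id = sprintf("i%02d", 40:1), modality = "DIHM",
                   evaluator = "e2", assigned_species = rev(b))
  expect_equal(cohen_kappa(ra, rb)$kappa, cohen_kappa(a, b)$kappa)
  rb_bad <- rb; rb_bad$image_id[1] <- "zzz"
  expect_error(cohen_kappa(ra, rb_bad), "unmatched")
  expect_error(cohen_kappa(c("a", "b"), c("a")), "equal length")
  # degenerate: both raters constant on the same label
  expect_equal(cohen_kappa(c("a", "a"), c("a", "a"))$kappa, 1)
})

test_that("kappa agrees with an exhaustive from-definition oracle", {
  # all 4096 pairs of binary label vectors of length 6
  labs <- c("p", "q")
  grid <- expand.grid(rep(list(1:2), 6))
  vecs <- lapply(seq_len(nrow(grid)), function(i) labs[unlist(grid[i, ])])
  oracle <- function(a, b) {
    n <- length(a)
    po <- sum(a == b) / n
    pe <- 0
    for (l in labs) pe <- pe + (sum(a == l) / n) * (sum(b == l) / n)
    # pe = 1 only when both vectors are constant on the same label (po = 1)
    if (abs(1 - pe) < 1e-15) return(1)
    (po - pe) / (1 - pe)
  }
  n_checked <- 0L
  worst <- 0
  for (i in seq_along(vecs)) for (j in seq_along(vecs)) {
    d <- abs(cohen_kappa(vecs[[i]], vecs[[j]])$kappa -
             oracle(vecs[[i]], vecs[[j]]))
    worst <- max(worst, d)
    n_checked <- n_checked + 1L
  }
  expect_equal(n_checked, 4096L)
  expect_lt(worst, 1e-12)
})

test_that("the study summary reproduces the benchmark table", {
  s <- summarize_study(pollen_study_records())
  get <- function(metric, modality, evaluator)
    s$value[s$metric == metric & s$modality == modality &
            s$evaluator == evaluator]
  expect_equal(get("accuracy", "DIHM", "expert1"), 97.9)
  expect_equal(get("accuracy", "DIHM", "expert2"), 93.8)
  expect_equal(get("accuracy", "optical", "expert1"), 95.8)
  expect_equal(get("accuracy", "optical", "expert2"), 97.9)
  expect_equal(get("pooled_accuracy", "DIHM", "all"), 95.8)
  expect_equal(get("pooled_accuracy", "optical", "all"), 96.9)
  # agreement statistics present and in range
  kappas <- s$value[grepl("kappa", s$metric)]
  expect_length(kappas, 6L)
  expect_true(all(kappas > 0.8 & kappas <= 1))

  # identity records: every accuracy 100, every kappa exactly 1
  ident <- summarize_study(generate_study_records(identity_study_spec()))
  expect_true(all(ident$value[grepl("accuracy", ident$metric)] == 100.0))
  expect_true(all(ident$value[grepl("kappa", ident$metric)] == 1.0))

  # single evaluator: kappa columns absent, accuracies present
  one <- pollen_study_records()
  one <- one[one$evaluator == "expert1" & one$modality == "DIHM", ]
  s1 <- summarize_study(one)
  expect_false(any(grepl("kappa", s1$metric)))
  expect_true(any(s1$metric == "accuracy"))
})
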