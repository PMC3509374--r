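make_sep_data <- function(seed, n1 = 8, n2 = 6, n_genes = 40,
                          n_informative = 20, effect = 3) {
  simulate_expression(n1 = n1, n2 = n2, n_genes = n_genes,
                      n_informative = n_informative, effect = effect,
                      seed = seed)
}

test_that("fitted centroids equal the training class means", {
  x <- rbind(g1 = c(1, 3, 2, 10, 12),
             g2 = c(5, 5, 5, 0, 0))
  colnames(x) <- paste0("s", 1:5)
  cv <- toy_labels(3, 2)
  sel <- select_genes(c(g1 = -0.9, g2 = 0.8), 0.5)
  model <- fit_classifier(x, cv, sel)
  expect_identical(model$gene_ids, c("g1", "g2"))
  expect_equal(unname(model$centroid_a), c(2, 5))
  expect_equal(unname(model$centroid_b), c(11, 0))
  expect_equal(unname(model$weights), c(0.9, 0.8))
  expect_error(fit_classifier(x, cv, select_genes(c(g1 = 0.1), 5)), "empty")
})

test_that("unselected genes play no role in the fitted model or predictions", {
  sim <- make_sep_data(1)
  scores <- snr_scores(sim$matrix, sim$labels)
  sel <- select_genes(scores, 0.5)
  expect_gt(nrow(sel), 0)
  model <- fit_classifier(sim$matrix, sim$labels, sel)
  perturbed <- sim$matrix
  others <- setdiff(rownames(perturbed), sel$gene_id)
  perturbed[others, ] <- perturbed[others, ] + 100
  expect_identical(fit_classifier(perturbed, sim$labels, sel), model)
  expect_identical(classify(model, perturbed), classify(model, sim$matrix))
})

test_that("classification follows the nearer centroid with deterministic ties", {
  x <- toy_matrix(c(0, 1, 2, 8, 9, 10), 1, 6, gene_ids = "g1")
  cv <- toy_labels(3, 3)
  model <- fit_classifier(x, cv, select_genes(snr_scores(x, cv), 0.5))

  at_a <- c(g1 = 1)
  pred <- classify(model, at_a)
  expect_identical(pred$class, "A")
  expect_gt(pred$margin, 0)

  beyond_b <- c(g1 = 30)
  expect_identical(classify(model, beyond_b)$class, "B")

  midpoint <- c(g1 = unname((model$centroid_a + model$centroid_b) / 2))
  expect_message(pred_tie <- classify(model, midpoint), "tie")
  expect_identical(pred_tie$class, "A")
  expect_equal(pred_tie$margin, 0)
})

test_that("samples lacking a model gene are rejected by name", {
  sim <- make_sep_data(2)
  sel <- select_genes(snr_scores(sim$matrix, sim$labels), 0.5)
  model <- fit_classifier(sim$matrix, sim$labels, sel)
  drop_gene <- model$gene_ids[1]
  expect_error(classify(model, sim$matrix[setdiff(rownames(sim$matrix),
                                                  drop_gene), ]),
               drop_gene)
})

test_that("flipping every label complements the error rate", {
  sim <- make_sep_data(3)
  sel <- select_genes(snr_scores(sim$matrix, sim$labels), 0.4)
  model <- fit_classifier(sim$matrix, sim$labels, sel)
  err <- error_rate(model, sim$matrix, sim$labels)
  # relabel every sample with the opposite class
  cls <- attr(sim$labels, "classes_ab")
  flipped <- class_vector(ifelse(unclass(sim$labels) == 1L, cls[2], cls[1]),
                          positive_class = cls[1],
                          sample_ids = names(sim$labels))
  expect_equal(error_rate(model, sim$matrix, flipped), 1 - err)
})

test_that("retrospective error is 0 on almost all strongly-separated replicates", {
  zero <- vapply(1:100, function(seed) {
    sim <- make_sep_data(seed + 500)
    scores <- snr_scores(sim$matrix, sim$labels)
    sel <- select_genes(scores, 0.5)
    model <- fit_classifier(sim$matrix, sim$labels, sel)
    error_rate(model, sim$matrix, sim$labels) == 0
  }, logical(1))
  expect_gte(mean(zero), 0.95)
})

test_that("predictions are invariant to per-gene affine rescaling of all data", {
  sim <- make_sep_data(4)
  scores <- snr_scores(sim$matrix, sim$labels)
  sel <- select_genes(scores, 0.5)
  model <- fit_classifier(sim$matrix, sim$labels, sel)

  set.seed(44)
  k <- runif(nrow(sim$matrix), 0.5, 3)
  b <- rnorm(nrow(sim$matrix))
  rescaled <- sim$matrix * k + b
  scores_r <- snr_scores(rescaled, sim$labels)
  sel_r <- select_genes(scores_r, 0.5)
  model_r <- fit_classifier(rescaled, sim$labels, sel_r)
  expect_identical(classify(model_r, rescaled)$class,
                   classify(model, sim$matrix)$class)
})

test_that("a coin-flip model errs near one half on balanced data", {
  # a model whose centroids coincide votes ties everywhere -> all class A,
  # so on a balanced cohort the error is exactly one half
  sim <- simulate_expression(n1 = 10, n2 = 10, n_genes = 20,
                             n_informative = 0, effect = 0, seed = 6)
  x0 <- sim$matrix
  model <- structure(
    list(gene_ids = rownames(x0)[1:5],
         centroid_a = rep(0, 5), centroid_b = rep(0, 5),
         weights = rep(1, 5),
         classes = attr(sim$labels, "classes_ab")),
    class = "centroid_model")
  suppressMessages(err <- error_rate(model, x0, sim$labels))
  expect_equal(err, 0.5)
})
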