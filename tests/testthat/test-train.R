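# fast, deliberately small training fixtures; the full-size ablation study
# runs in the acceptance suite
train_bundle <- function(...) {
  synth_bundle(synth_config(n_entities = 6, n_train = 40, n_dev = 10,
                            n_test = 20, vocab_size = 80, seed = 17, ...))
}

fast_cfg <- function(..., epochs = 4) {
  kgner_config(dim = 16, head_dim = 8, heads = 2, fusion_dim = 16,
               epochs = epochs, batch_size = 8, ...)
}

test_that("a small model memorizes a toy corpus", {
  fit <- kgner_train(toy_corpus(), kg = NULL,
                     config = kgner_config(ablation = "none", epochs = 60,
                                           batch_size = 2, dropout = 0,
                                           dim = 16, fusion_dim = 16, seed = 1))
  pred <- predict(fit, toy_corpus())
  expect_equal(mean(pred$.pred == toy_corpus()$label), 1)
  # loss decreased over training
  r <- tidy(fit)
  expect_lt(r$loss[nrow(r)], r$loss[1])
})

test_that("optimization reduces the loss across seeds", {
  b <- train_bundle()
  for (seed in 1:3) {
    fit <- kgner_train(b$train, kg = b$kg,
                       config = fast_cfg(ablation = "relation", seed = seed,
                                         epochs = 3))
    r <- tidy(fit)
    expect_lt(r$loss[3], r$loss[1])
  }
})

test_that("training and prediction are deterministic given the seed", {
  b <- train_bundle()
  cfg <- fast_cfg(ablation = "relation", seed = 5, epochs = 2)
  fit1 <- kgner_train(b$train, kg = b$kg, dev = b$dev, config = cfg)
  fit2 <- kgner_train(b$train, kg = b$kg, dev = b$dev, config = cfg)
  expect_identical(tidy(fit1), tidy(fit2))
  p1 <- predict(fit1, b$test, kg = b$kg)
  p2 <- predict(fit2, b$test, kg = b$kg)
  expect_identical(p1$.pred, p2$.pred)
})

test_that("zeroing the knowledge projection reproduces the no-knowledge path", {
  b <- train_bundle()
  fit <- kgner_train(b$train, kg = b$kg,
                     config = fast_cfg(ablation = "relation", seed = 2,
                                       epochs = 2))
  # same parameters, knowledge channel silenced two different ways
  cut <- fit
  cut$model$w2 <- cut$model$w2 * 0
  skipped <- cut
  skipped$model$config$ablation <- "none"
  p_zeroed <- predict(cut, b$test, kg = b$kg)
  p_skipped <- predict(skipped, b$test)
  expect_identical(p_zeroed$.pred, p_skipped$.pred)
})

test_that("an unmatchable knowledge graph reduces to the no-knowledge output", {
  b <- train_bundle()
  fit <- kgner_train(b$train, kg = b$kg,
                     config = fast_cfg(ablation = "relation", seed = 3,
                                       epochs = 2))
  kg_empty <- kg_new(tibble::tibble(surface = "zzzzqqq", category = "Drug"))
  p_unmatched <- predict(fit, b$test, kg = kg_empty)
  none <- fit
  none$model$config$ablation <- "none"
  p_none <- predict(none, b$test)
  expect_identical(p_unmatched$.pred, p_none$.pred)
})

test_that("prediction batching cannot change results and outputs stay legal", {
  b <- train_bundle()
  fit <- kgner_train(b$train, kg = b$kg,
                     config = fast_cfg(ablation = "relation", seed = 4,
                                       epochs = 2))
  whole <- predict(fit, b$test, kg = b$kg)
  ids <- unique(b$test$sentence_id)
  for (id in ids[1:5]) {
    one <- predict(fit, b$test[b$test$sentence_id == id, ], kg = b$kg)
    expect_identical(one$.pred, whole$.pred[whole$sentence_id == id])
  }
  # every decoded sentence is legal BIO
  labs <- split(whole$.pred, factor(whole$sentence_id, unique(whole$sentence_id)))
  for (l in labs) expect_silent(bio_validate(l))
  # single-token sentences decode to a single legal tag
  single <- tibble::tibble(sentence_id = c("a", "b"), token = c("x", "y"))
  ps <- predict(fit, single, kg = b$kg)
  expect_equal(nrow(ps), 2)
  expect_true(all(ps$.pred %in% c("O", grep("^B", fit$model$labels, value = TRUE))))
})

test_that("overlong sentences are truncated with a warning, dropping cut spans", {
  data <- tibble::tibble(
    sentence_id = "s1",
    token = sprintf("w%d", 1:8),
    label = c("O", "B-D", "I-D", "O", "O", "B-D", "I-D", "I-D"))
  expect_warning(
    fit <- kgner_train(data, kg = NULL,
                       config = kgner_config(ablation = "none", epochs = 1,
                                             max_len = 6, dim = 4,
                                             fusion_dim = 4, seed = 1)),
    class = "kgner_truncated")
  # the span crossing the cut was dropped from the training labels
  expect_equal(kgner:::truncate_sentence(data$token, data$label, 6)$labels,
               c("O", "B-D", "I-D", "O", "O", "O"))
})

test_that("checkpoints round-trip and refuse unknown versions", {
  b <- train_bundle()
  fit <- kgner_train(b$train, kg = b$kg,
                     config = fast_cfg(ablation = "relation", seed = 6,
                                       epochs = 1))
  path <- withr::local_tempfile(fileext = ".rds")
  kgner_save(fit, path)
  back <- kgner_load(path)
  expect_identical(predict(back, b$test, kg = b$kg)$.pred,
                   predict(fit, b$test, kg = b$kg)$.pred)
  saveRDS(list(version = "other", fit = NULL), path)
  expect_error(kgner_load(path), class = "kgner_bad_checkpoint")
})

test_that("tidiers and plots expose the training trajectory", {
  b <- train_bundle()
  fit <- kgner_train(b$train, kg = b$kg, dev = b$dev,
                     config = fast_cfg(ablation = "relation", seed = 7,
                                       epochs = 2))
  r <- tidy(fit)
  expect_equal(nrow(r), 2)
  expect_true(all(c("epoch", "loss", "dev_f1") %in% names(r)))
  g <- glance(fit)
  expect_equal(g$epochs, 2)
  expect_equal(g$ablation, "relation")
  expect_s3_class(autoplot(fit), "ggplot")
  m <- ner_evaluate(predict(fit, b$test, kg = b$kg))
  expect_s3_class(autoplot(m), "ggplot")
})

test_that("end-to-end gradients match finite differences on a tiny model", {
  b <- train_bundle()
  cfg <- kgner_config(dim = 4, head_dim = 3, heads = 2, fusion_dim = 4,
                      ablation = "relation", seed = 8)
  corpus <- b$train[b$train$sentence_id %in% unique(b$train$sentence_id)[1:2], ]
  sent <- kgner:::corpus_to_sentences(corpus)
  labels <- sort(unique(c("O", unlist(sent$labels))))
  vocab <- unique(c(tolower(unlist(sent$tokens)),
                    unlist(strsplit(kgner:::normalize_surface(
                      b$kg$nodes$surface), " "))))
  model <- kgner:::new_model(vocab, labels, cfg)
  preps <- lapply(seq_along(sent$tokens), function(i)
    kgner:::prep_sentence(sent$tokens[[i]], sent$labels[[i]], model, b$kg))
  # make sure the fixture actually exercises the knowledge path
  expect_true(any(vapply(preps, function(p)
    length(p$graph$node_ids) > 0, logical(1))))
  g <- kgner:::model_grads(model, preps, dropout = 0)
  params <- kgner:::get_flat_params(model)
  loss_at <- function(p) {
    m2 <- kgner:::set_flat_params(model, p)
    kgner:::model_grads(m2, preps, dropout = 0)$loss
  }
  for (nm in names(params)) {
    num <- numeric_grad(function(x) {
      p <- params; p[[nm]] <- x; loss_at(p)
    }, params[[nm]], eps = 1e-5)
    expect_equal(g$grads[[nm]], num, tolerance = 1e-4,
                 label = paste("gradient of", nm))
  }
})
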