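# A tiny cohort + model shared across the encoder tests.
enc_fixture <- function(n = 12, d = 8, heads = 2, seed = 41, dropout = 0) {
  sim <- generate_cohort(default_synth_config(n, seed = seed))
  vocab <- build_vocabulary(sim$cohort, min_code_count = 1)
  seqs <- tokenise_cohort(sim$cohort, vocab, max_len = 32)
  cfg <- encoder_config(d_model = d, n_layers = 2, n_heads = heads, d_ff = 2 * d,
                        max_len = 32, dropout = dropout, seed = seed)
  list(seqs = seqs, vocab = vocab, cfg = cfg,
       model = init_encoder(cfg, vocab))
}

test_that("inference-mode encoding is deterministic and masks nothing it shouldn't", {
  fx <- enc_fixture()
  s <- fx$seqs[[1]]
  o1 <- embed_sequence(s, fx$model)
  o2 <- embed_sequence(s, fx$model)
  expect_identical(o1, o2)
  expect_length(o1, fx$cfg$n_layers + 1)
  expect_equal(dim(o1[[1]]), c(length(s$token_ids), fx$cfg$d_model))
})

test_that("the visit-position channel is live: permuting visit ids changes outputs", {
  fx <- enc_fixture()
  s <- fx$seqs[[which.max(vapply(fx$seqs, function(x) length(x$token_ids), numeric(1)))]]
  stopifnot(length(s$token_ids) >= 4)
  s2 <- s
  # swap the visit ids of two tokens with different visits, keeping codes fixed
  i <- which(diff(s$visit_ids) > 0)[2]
  s2$visit_ids[c(i, i + 1)] <- s2$visit_ids[c(i + 1, i)]
  v1 <- pool_patient_vector(embed_sequence(s, fx$model))
  v2 <- pool_patient_vector(embed_sequence(s2, fx$model))
  expect_false(isTRUE(all.equal(v1, v2)))
})

test_that("out-of-range token ids name the offending stream", {
  fx <- enc_fixture()
  s <- fx$seqs[[1]]
  s$token_ids[1] <- fx$model$dims$n_token
  expect_error(embed_sequence(s, fx$model), "token_ids")
  s <- fx$seqs[[1]]
  s$age_ids[1] <- -1L
  expect_error(embed_sequence(s, fx$model), "age_ids")
})

test_that("pooling averages first and final layers over token positions", {
  # hand instance: T = 1, first layer (1,0), final (0,1) -> (0.5, 0.5)
  outs <- structure(list(matrix(c(9, 9), 1), matrix(c(1, 0), 1), matrix(c(0, 1), 1)),
                    class = "layer_outputs")
  expect_equal(pool_patient_vector(outs), c(0.5, 0.5))
  # first = final everywhere -> token mean of that layer
  h <- matrix(rnorm(12), 4, 3)
  outs2 <- structure(list(matrix(0, 4, 3), h, h), class = "layer_outputs")
  expect_equal(pool_patient_vector(outs2), colMeans(h))
  # brute-force elementwise oracle on a random fixture
  fx <- enc_fixture()
  o <- embed_sequence(fx$seqs[[2]], fx$model)
  manual <- colMeans((o[[2]] + o[[3]]) / 2)
  expect_equal(pool_patient_vector(o), manual)
  # pooling linearity: pool(H + c) = pool(H) + c
  oc <- structure(list(o[[1]], o[[2]] + 2, o[[3]] + 2), class = "layer_outputs")
  expect_equal(pool_patient_vector(oc), pool_patient_vector(o) + 2)
})

test_that("InfoNCE matches its analytic identities and a hand evaluation", {
  # uniform similarities: loss = log N exactly (vectors identical)
  A <- matrix(rep(c(1, 0), each = 4), 4, 2)
  expect_equal(contrastive_loss(A, A, tau = 1), log(4))
  # perfect diagonal, tiny temperature: loss -> 0
  B <- diag(3)
  expect_lt(contrastive_loss(B, B, tau = 0.01), 1e-6)
  # hand-set cosine-similarity matrix [[0.9, 0.1], [0.2, 0.8]], tau = 1,
  # realised exactly with orthogonal unit anchors and 3-D unit positives
  A3 <- rbind(c(1, 0, 0), c(0, 1, 0))
  P3 <- rbind(c(0.9, 0.2, sqrt(1 - 0.9^2 - 0.2^2)),
              c(0.1, 0.8, sqrt(1 - 0.1^2 - 0.8^2)))
  manual <- -(log(exp(0.9) / (exp(0.9) + exp(0.1))) +
                log(exp(0.8) / (exp(0.2) + exp(0.8)))) / 2
  expect_equal(contrastive_loss(A3, P3, tau = 1), manual)
  # degenerate inputs
  expect_error(contrastive_loss(matrix(0, 2, 2), diag(2), 1), "zero-norm")
  expect_error(contrastive_loss(diag(2)[1, , drop = FALSE],
                                diag(2)[1, , drop = FALSE], 1), "at least 2")
})

test_that("analytic gradients match central finite differences", {
  fx <- enc_fixture(n = 6, d = 4, heads = 2)
  s1 <- fx$seqs[[1]]; s2 <- fx$seqs[[2]]
  model <- fx$model
  pool2 <- function(f) colMeans((f$layers[[2]] + f$layers[[3]]) / 2)
  loss_of <- function(m) {
    A <- rbind(pool2(hfsubtype:::encoder_forward(m, s1)),
               pool2(hfsubtype:::encoder_forward(m, s2)))
    contrastive_loss(A, A[c(2, 1), ] + 0.25, tau = 0.5)
  }
  f1 <- hfsubtype:::encoder_forward(model, s1)
  f2 <- hfsubtype:::encoder_forward(model, s2)
  A <- rbind(pool2(f1), pool2(f2)); P <- A[c(2, 1), ] + 0.25
  nce <- hfsubtype:::info_nce(A, P, 0.5)
  g <- hfsubtype:::add_params(
    hfsubtype:::encoder_backward(model, f1, nce$dA[1, ] + nce$dP[2, ], 1),
    hfsubtype:::encoder_backward(model, f2, nce$dA[2, ] + nce$dP[1, ], 1))
  eps <- 1e-5
  probe <- list(
    list(NULL, "emb_code", s1$token_ids[2] + 1L),
    list(NULL, "emb_visit", 2L),
    list(1L, "Wv", 5L), list(2L, "Wq", 3L), list(1L, "Wo", 7L),
    list(2L, "W1", 11L), list(1L, "W2", 4L),
    list(1L, "ln1_g", 2L), list(2L, "ln2_b", 3L))
  for (pr in probe) {
    bump <- function(m, delta) {
      if (is.null(pr[[1]])) m$params[[pr[[2]]]][pr[[3]]] <- m$params[[pr[[2]]]][pr[[3]]] + delta
      else m$params$layers[[pr[[1]]]][[pr[[2]]]][pr[[3]]] <-
          m$params$layers[[pr[[1]]]][[pr[[2]]]][pr[[3]]] + delta
      m
    }
    ga <- if (is.null(pr[[1]])) g[[pr[[2]]]][pr[[3]]] else g$layers[[pr[[1]]]][[pr[[2]]]][pr[[3]]]
    gn <- (loss_of(bump(model, eps)) - loss_of(bump(model, -eps))) / (2 * eps)
    expect_equal(ga, gn, tolerance = 1e-5,
                 label = sprintf("gradient of %s", pr[[2]]))
  }
})

test_that("positive-pair construction produces the advertised views", {
  fx <- enc_fixture(dropout = 0.2)
  s <- fx$seqs[[1]]
  withr::with_seed(1, {
    pair <- make_positive_pair(s, fx$model, mode = "dropout-twin")
    expect_false(isTRUE(all.equal(pair$anchor, pair$positive)))
  })
  # dropout-twin with p = 0 is degenerate
  fx0 <- enc_fixture(dropout = 0)
  expect_error(make_positive_pair(fx0$seqs[[1]], fx0$model, mode = "dropout-twin"),
               "dropout")
  # span-mask rate 0: both views equal the clean encoding
  withr::with_seed(2, {
    pair0 <- make_positive_pair(fx0$seqs[[1]], fx0$model, mode = "span-mask",
                                mask_rate = 0)
  })
  clean <- pool_patient_vector(embed_sequence(fx0$seqs[[1]], fx0$model))
  expect_equal(pair0$anchor, clean)
  expect_equal(pair0$positive, clean)
})

test_that("span-mask replaces exactly the rounded count of event tokens", {
  fx <- enc_fixture()
  s <- fx$seqs[[1]]
  s$token_ids <- c(1L, rep(5L, 20))   # CLS + 20 event tokens, no natural UNKs
  s$age_ids <- rep(40L, 21); s$year_ids <- rep(0L, 21); s$visit_ids <- 0:20
  masked <- withr::with_seed(3, hfsubtype:::span_mask(s, 0.15))
  expect_equal(sum(masked$token_ids == 3L), 3)    # floor(0.15 * 20 + 0.5) = 3
  expect_equal(masked$token_ids[1], 1L)            # CLS never masked
})

test_that("training reduces the contrastive loss and is seed-reproducible", {
  sim <- generate_cohort(default_synth_config(120, seed = 43))
  vocab <- build_vocabulary(sim$cohort, min_code_count = 2)
  seqs <- tokenise_cohort(sim$cohort, vocab, max_len = 48)
  cfg <- encoder_config(d_model = 16, n_layers = 2, n_heads = 2, d_ff = 32,
                        max_len = 48, batch_size = 32, n_epochs = 2, seed = 44)
  m1 <- train_encoder(seqs, cfg, vocab)
  expect_lt(m1$log$mean_loss[2], m1$log$mean_loss[1])
  m2 <- train_encoder(seqs, cfg, vocab)
  expect_identical(m1$log, m2$log)
  expect_identical(m1$params$emb_code, m2$params$emb_code)
  expect_error(train_encoder(seqs, encoder_config(batch_size = 1), vocab),
               "batch_size")
})

test_that("checkpoints round-trip through the JSON format", {
  fx <- enc_fixture(n = 6, d = 4, heads = 2)
  path <- withr::local_tempfile(fileext = ".json")
  save_encoder(fx$model, path)
  back <- load_encoder(path)
  expect_equal(back$params, fx$model$params)
  s <- fx$seqs[[1]]
  expect_equal(pool_patient_vector(embed_sequence(s, back)),
               pool_patient_vector(embed_sequence(s, fx$model)))
})
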