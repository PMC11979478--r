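# Analytic backpropagation, Adam, and the contrastive training loop for the
# transformer encoder. Gradients are verified against central finite
# differences in the test suite.

zero_like <- function(p) {
  if (is.list(p)) lapply(p, zero_like)
  else if (is.matrix(p)) matrix(0, nrow(p), ncol(p))
  else numeric(length(p))
}

map2_params <- function(a, b, f) {
  if (is.list(a)) {
    out <- vector("list", length(a))
    names(out) <- names(a)
    for (i in seq_along(a)) out[[i]] <- map2_params(a[[i]], b[[i]], f)
    out
  } else f(a, b)
}

add_params <- function(a, b) map2_params(a, b, `+`)

# backward through row-wise layer norm; returns dx and parameter grads
ln_backward <- function(dy, ln, g) {
  dxhat <- sweep(dy, 2, g, `*`)
  dx <- (dxhat - rowMeans(dxhat) - ln$xhat * rowMeans(dxhat * ln$xhat)) * ln$isig
  list(dx = dx, dg = colSums(dy * ln$xhat), db = colSums(dy))
}

# gradient of one forward pass wrt all parameters, given the gradient of the
# loss wrt that sequence's pooled patient vector
encoder_backward <- function(model, fwd, dpool, first = 1L) {
  cfg <- model$config
  p <- model$params
  T_len <- nrow(fwd$layers[[1]])
  d <- cfg$d_model
  L <- cfg$n_layers
  dh <- d %/% cfg$n_heads
  grads <- zero_like(p)
  # pooling: mean over tokens of (H_first + H_final)/2
  pool_term <- matrix(dpool / (2 * T_len), T_len, d, byrow = TRUE)
  dH <- pool_term
  if (first == L) dH <- dH + pool_term  # degenerate single-layer pooling
  for (l in rev(seq_len(L))) {
    cc <- fwd$caches[[l]]
    lp <- p$layers[[l]]
    g <- list()
    b2 <- ln_backward(dH, cc$ln2, lp$ln2_g)
    g$ln2_g <- b2$dg; g$ln2_b <- b2$db
    dU <- b2$dx
    dZ <- dU
    dF <- apply_mask(dU, cc$mask_f)
    g$W2 <- t(cc$R) %*% dF
    g$b2 <- colSums(dF)
    dR <- dF %*% t(lp$W2)
    dG <- dR * cc$relu_mask
    g$W1 <- t(cc$Z) %*% dG
    g$b1 <- colSums(dG)
    dZ <- dZ + dG %*% t(lp$W1)
    b1 <- ln_backward(dZ, cc$ln1, lp$ln1_g)
    g$ln1_g <- b1$dg; g$ln1_b <- b1$db
    dM <- b1$dx
    dH_in <- dM
    dAout <- apply_mask(dM, cc$mask_a)
    dO <- dAout %*% t(lp$Wo)
    g$Wo <- t(cc$O) %*% dAout
    g$bo <- colSums(dAout)
    dQ <- matrix(0, T_len, d); dK <- matrix(0, T_len, d); dV <- matrix(0, T_len, d)
    for (h in seq_len(cfg$n_heads)) {
      cols <- ((h - 1L) * dh + 1L):(h * dh)
      A <- cc$A_heads[[h]]
      dO_h <- dO[, cols, drop = FALSE]
      Vh <- cc$V[, cols, drop = FALSE]
      dA <- dO_h %*% t(Vh)
      dV[, cols] <- t(A) %*% dO_h
      dSc <- (A * (dA - rowSums(A * dA))) / sqrt(dh)
      dQ[, cols] <- dSc %*% cc$K[, cols, drop = FALSE]
      dK[, cols] <- t(dSc) %*% cc$Q[, cols, drop = FALSE]
    }
    g$Wq <- t(cc$H_in) %*% dQ; g$bq <- colSums(dQ)
    g$Wk <- t(cc$H_in) %*% dK; g$bk <- colSums(dK)
    g$Wv <- t(cc$H_in) %*% dV; g$bv <- colSums(dV)
    dH_in <- dH_in + dQ %*% t(lp$Wq) + dK %*% t(lp$Wk) + dV %*% t(lp$Wv)
    grads$layers[[l]] <- g[names(p$layers[[l]])]  # align element order with params
    dH <- dH_in
    # after backprop of layer l, dH is the grad wrt layers[[l]] = H^(l-1);
    # add the pooling contribution when that is the pooled "first" layer
    if (l - 1L == first) dH <- dH + pool_term
  }
  dE <- apply_mask(dH, fwd$mask0)
  seq <- fwd$seq
  acc_emb <- function(tbl, ids) {
    gt <- rowsum(dE, ids + 1L)
    rows <- as.integer(rownames(gt))
    tbl[rows, ] <- tbl[rows, , drop = FALSE] + gt
    tbl
  }
  grads$emb_code <- acc_emb(grads$emb_code, seq$token_ids)
  grads$emb_age <- acc_emb(grads$emb_age, seq$age_ids)
  grads$emb_year <- acc_emb(grads$emb_year, seq$year_ids)
  grads$emb_visit <- acc_emb(grads$emb_visit, seq$visit_ids)
  grads
}

adam_init <- function(params) list(m = zero_like(params), v = zero_like(params), t = 0L)

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- map2_params(state$m, grads, function(m, g) beta1 * m + (1 - beta1) * g)
  state$v <- map2_params(state$v, grads, function(v, g) beta2 * v + (1 - beta2) * g^2)
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  upd <- map2_params(state$m, state$v, function(m, v) (m / c1) / (sqrt(v / c2) + eps))
  params <- map2_params(params, upd, function(p, u) p - lr * u)
  list(params = params, state = state)
}

#' Train the encoder with the contrastive objective
#'
#' Minimises the InfoNCE loss over shuffled mini-batches of positive pairs
#' (two stochastic views per patient, in-batch negatives) with Adam.
#' Training is fully seeded: the same sequences, config and seed reproduce
#' the same model and loss trajectory. Train only on derivation-cohort
#' sequences; validation hygiene is asserted by the pipeline.
#'
#' @param seqs Named list of `token_sequence`s (derivation cohort).
#' @param config An [encoder_config()].
#' @param vocab The `ehr_vocab` used to tokenise (sizes the embedding
#'   tables).
#' @param model Optionally a pre-initialised `hf_encoder` to continue
#'   training.
#' @return A trained `hf_encoder`; `$log` holds a tibble (epoch, mean_loss).
#' @export
train_encoder <- function(seqs, config, vocab = NULL, model = NULL) {
  if (config$batch_size < 2) abort("`batch_size` must be >= 2 for in-batch negatives")
  if (config$pair_mode == "dropout-twin" && config$dropout <= 0) {
    abort("dropout-twin training needs dropout > 0")
  }
  model <- model %||% init_encoder(config, vocab)
  first <- pool_first_index(config)
  n <- length(seqs)
  if (n < config$batch_size) {
    warn("fewer sequences than batch_size; training with one smaller batch")
  }
  epoch_loss <- numeric(config$n_epochs)
  adam <- adam_init(model$params)
  with_seed(derive_seed(config$seed, "train"), {
    for (epoch in seq_len(config$n_epochs)) {
      perm <- sample.int(n)
      batches <- split(perm, ceiling(seq_along(perm) / config$batch_size))
      losses <- c()
      for (batch in batches) {
        nb <- length(batch)
        if (nb < 2) next
        fwd1 <- vector("list", nb); fwd2 <- vector("list", nb)
        A <- matrix(0, nb, config$d_model); P <- matrix(0, nb, config$d_model)
        for (i in seq_len(nb)) {
          s <- seqs[[batch[i]]]
          if (config$pair_mode == "dropout-twin") {
            fwd1[[i]] <- encoder_forward(model, s, train = TRUE)
            fwd2[[i]] <- encoder_forward(model, s, train = TRUE)
          } else {
            fwd1[[i]] <- encoder_forward(model, span_mask(s, config$mask_rate), train = FALSE)
            fwd2[[i]] <- encoder_forward(model, span_mask(s, config$mask_rate), train = FALSE)
          }
          A[i, ] <- colMeans((fwd1[[i]]$layers[[first + 1L]] +
                                fwd1[[i]]$layers[[config$n_layers + 1L]]) / 2)
          P[i, ] <- colMeans((fwd2[[i]]$layers[[first + 1L]] +
                                fwd2[[i]]$layers[[config$n_layers + 1L]]) / 2)
        }
        nce <- info_nce(A, P, config$tau)
        grads <- zero_like(model$params)
        for (i in seq_len(nb)) {
          grads <- add_params(grads, encoder_backward(model, fwd1[[i]], nce$dA[i, ], first))
          grads <- add_params(grads, encoder_backward(model, fwd2[[i]], nce$dP[i, ], first))
        }
        stepped <- adam_step(model$params, grads, adam, config$learning_rate)
        model$params <- stepped$params
        adam <- stepped$state
        losses <- c(losses, nce$loss)
      }
      epoch_loss[epoch] <- mean(losses)
    }
  })
  model$trained <- TRUE
  model$log <- tibble(epoch = seq_len(config$n_epochs), mean_loss = epoch_loss)
  model
}
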