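#' Configuration of the transformer patient encoder
#'
#' The encoder embeds each clinical event as the sum of four learned
#' embeddings — code, age at event (1-year buckets), calendar year, and visit
#' position — and passes the sequence through a stack of standard
#' self-attention encoder layers (multi-head attention, position-wise
#' feed-forward, residual connections, layer normalisation). Patient vectors
#' are pooled from the first and final layer outputs and the model is trained
#' with an InfoNCE contrastive objective over positive pairs built from two
#' stochastic views of the same patient.
#'
#' Defaults are desk-scale: a 2-layer, 32-dimensional model trainable on one
#' CPU in minutes.
#'
#' @param d_model Embedding width (divisible by `n_heads`).
#' @param n_layers Number of encoder layers (>= 1; with 1 layer the
#'   first/final pooling degenerates to a single layer).
#' @param n_heads Attention heads.
#' @param d_ff Feed-forward inner width (default `2 * d_model`).
#' @param max_len Maximum token-sequence length (including CLS).
#' @param dropout Dropout rate `p` used in training and for dropout-twin
#'   positive pairs.
#' @param tau Contrastive softmax temperature (> 0).
#' @param batch_size Contrastive batch size (>= 2: in-batch negatives).
#' @param learning_rate Adam step size.
#' @param n_epochs Training epochs.
#' @param pair_mode `"dropout-twin"` (two dropout views of one sequence) or
#'   `"span-mask"` (random event tokens replaced by UNK in each view).
#' @param mask_rate Fraction of event tokens masked per view in span-mask
#'   mode (count = `floor(rate * n_events + 0.5)`).
#' @param pool_first Which layer acts as the "first" pooling layer:
#'   `"encoder1"` (output of the first encoder layer, default) or
#'   `"embedding"` (the embedding-layer output).
#' @param seed Seed controlling initialisation and training stochasticity.
#' @return An `encoder_config` list.
#' @export
encoder_config <- function(d_model = 32L, n_layers = 2L, n_heads = 4L,
                           d_ff = 2L * d_model, max_len = 64L,
                           dropout = 0.1, tau = 0.05,
                           batch_size = 64L, learning_rate = 1e-3,
                           n_epochs = 3L,
                           pair_mode = c("dropout-twin", "span-mask"),
                           mask_rate = 0.15,
                           pool_first = c("encoder1", "embedding"),
                           seed = 1L) {
  if (d_model %% n_heads != 0) abort("`d_model` must be divisible by `n_heads`")
  if (tau <= 0) abort("`tau` must be > 0")
  if (n_layers < 1) abort("`n_layers` must be >= 1")
  if (dropout < 0 || dropout >= 1) abort("`dropout` must be in [0, 1)")
  structure(list(
    d_model = as.integer(d_model), n_layers = as.integer(n_layers),
    n_heads = as.integer(n_heads), d_ff = as.integer(d_ff),
    max_len = as.integer(max_len), dropout = dropout, tau = tau,
    batch_size = as.integer(batch_size), learning_rate = learning_rate,
    n_epochs = as.integer(n_epochs),
    pair_mode = match.arg(pair_mode), mask_rate = mask_rate,
    pool_first = match.arg(pool_first), seed = as.integer(seed)
  ), class = "encoder_config")
}

#' Initialise an untrained encoder
#'
#' Weights are drawn N(0, 0.02^2); layer-norm gains start at 1 and biases at
#' 0. Embedding-table sizes come from the vocabulary (codes + reserved
#' tokens, ages up to the cap, observed year range, visit positions up to
#' `max_len`).
#'
#' @param config An [encoder_config()].
#' @param vocab An `ehr_vocab`.
#' @return An `hf_encoder` model (untrained).
#' @export
init_encoder <- function(config, vocab) {
  stopifnot(inherits(config, "encoder_config"), inherits(vocab, "ehr_vocab"))
  d <- config$d_model
  dims <- list(
    n_token = vocab_size(vocab),
    n_age = vocab$age_cap + 1L,
    n_year = vocab$year_max - vocab$year_min + 1L,
    n_visit = config$max_len + 1L
  )
  with_seed(derive_seed(config$seed, "init"), {
    rmat <- function(nr, nc) matrix(rnorm(nr * nc, sd = 0.02), nr, nc)
    layer <- function() list(
      Wq = rmat(d, d), bq = numeric(d), Wk = rmat(d, d), bk = numeric(d),
      Wv = rmat(d, d), bv = numeric(d), Wo = rmat(d, d), bo = numeric(d),
      ln1_g = rep(1, d), ln1_b = numeric(d),
      W1 = rmat(d, config$d_ff), b1 = numeric(config$d_ff),
      W2 = rmat(config$d_ff, d), b2 = numeric(d),
      ln2_g = rep(1, d), ln2_b = numeric(d))
    params <- list(
      emb_code = rmat(dims$n_token, d),
      emb_age = rmat(dims$n_age, d),
      emb_year = rmat(dims$n_year, d),
      emb_visit = rmat(dims$n_visit, d),
      layers = lapply(seq_len(config$n_layers), function(i) layer()))
    structure(list(params = params, config = config, dims = dims,
                   trained = FALSE, log = NULL),
              class = "hf_encoder")
  })
}

#' @export
print.hf_encoder <- function(x, ...) {
  cat(sprintf("<hf_encoder> d=%d, layers=%d, heads=%d (%s)\n",
              x$config$d_model, x$config$n_layers, x$config$n_heads,
              if (isTRUE(x$trained)) "trained" else "untrained"))
  invisible(x)
}

ln_eps <- 1e-5

# row-wise layer normalisation; returns output plus backward cache
layer_norm <- function(x, g, b) {
  mu <- rowMeans(x)
  xc <- x - mu
  isig <- 1 / sqrt(rowMeans(xc^2) + ln_eps)
  xhat <- xc * isig
  list(y = sweep(xhat, 2, g, `*`) + rep(b, each = nrow(x)),
       xhat = xhat, isig = isig)
}

softmax_rows <- function(x) {
  m <- apply(x, 1, max)
  e <- exp(x - m)
  e / rowSums(e)
}

make_dropout_mask <- function(nr, nc, p) {
  if (p <= 0) return(NULL)
  matrix((runif(nr * nc) >= p) / (1 - p), nr, nc)
}

apply_mask <- function(x, mask) if (is.null(mask)) x else x * mask

#' Run a token sequence through the encoder
#'
#' Sums the four embedding streams per token and applies the encoder stack,
#' returning the output of every layer (`H0` is the embedding-layer output,
#' `H1..HL` the encoder layers). Deterministic in inference mode
#' (`train = FALSE`, the default).
#'
#' @param seq A `token_sequence`.
#' @param model An `hf_encoder`.
#' @param train Apply dropout (TRUE only during training).
#' @return A `layer_outputs` object: list of `L + 1` matrices `T x d_model`,
#'   with the forward cache attached when `train`-mode callers need it.
#' @export
embed_sequence <- function(seq, model, train = FALSE) {
  stopifnot(inherits(seq, "token_sequence"), inherits(model, "hf_encoder"))
  fwd <- encoder_forward(model, seq, train = train)
  structure(fwd$layers, class = "layer_outputs", cache = if (train) fwd else NULL)
}

# Full forward pass with caches for backprop.
encoder_forward <- function(model, seq, train = FALSE) {
  p <- model$params
  cfg <- model$config
  check_stream <- function(ids, n, name) {
    if (any(ids < 0L) || any(ids >= n)) {
      abort(sprintf("token id out of range in stream `%s` (valid 0..%d)", name, n - 1L))
    }
  }
  check_stream(seq$token_ids, model$dims$n_token, "token_ids")
  check_stream(seq$age_ids, model$dims$n_age, "age_ids")
  check_stream(seq$year_ids, model$dims$n_year, "year_ids")
  check_stream(seq$visit_ids, model$dims$n_visit, "visit_ids")
  T_len <- length(seq$token_ids)
  d <- cfg$d_model
  E <- p$emb_code[seq$token_ids + 1L, , drop = FALSE] +
    p$emb_age[seq$age_ids + 1L, , drop = FALSE] +
    p$emb_year[seq$year_ids + 1L, , drop = FALSE] +
    p$emb_visit[seq$visit_ids + 1L, , drop = FALSE]
  drop_p <- if (train) cfg$dropout else 0
  mask0 <- make_dropout_mask(T_len, d, drop_p)
  H <- apply_mask(E, mask0)
  layers <- vector("list", cfg$n_layers + 1L)
  caches <- vector("list", cfg$n_layers)
  layers[[1]] <- H
  dh <- d %/% cfg$n_heads
  for (l in seq_len(cfg$n_layers)) {
    lp <- p$layers[[l]]
    Q <- H %*% lp$Wq + rep(lp$bq, each = T_len)
    K <- H %*% lp$Wk + rep(lp$bk, each = T_len)
    V <- H %*% lp$Wv + rep(lp$bv, each = T_len)
    A_heads <- vector("list", cfg$n_heads)
    O <- matrix(0, T_len, d)
    for (h in seq_len(cfg$n_heads)) {
      cols <- ((h - 1L) * dh + 1L):(h * dh)
      S <- (Q[, cols, drop = FALSE] %*% t(K[, cols, drop = FALSE])) / sqrt(dh)
      A <- softmax_rows(S)
      A_heads[[h]] <- A
      O[, cols] <- A %*% V[, cols, drop = FALSE]
    }
    Aout <- O %*% lp$Wo + rep(lp$bo, each = T_len)
    mask_a <- make_dropout_mask(T_len, d, drop_p)
    M <- H + apply_mask(Aout, mask_a)
    ln1 <- layer_norm(M, lp$ln1_g, lp$ln1_b)
    Z <- ln1$y
    G <- Z %*% lp$W1 + rep(lp$b1, each = T_len)
    R <- pmax(G, 0)
    Ff <- R %*% lp$W2 + rep(lp$b2, each = T_len)
    mask_f <- make_dropout_mask(T_len, cfg$d_model, drop_p)
    U <- Z + apply_mask(Ff, mask_f)
    ln2 <- layer_norm(U, lp$ln2_g, lp$ln2_b)
    caches[[l]] <- list(H_in = H, Q = Q, K = K, V = V, A_heads = A_heads, O = O,
                        mask_a = mask_a, ln1 = ln1, Z = Z, relu_mask = G > 0,
                        R = R, mask_f = mask_f, ln2 = ln2)
    H <- ln2$y
    layers[[l + 1L]] <- H
  }
  list(layers = layers, caches = caches, mask0 = mask0, seq = seq)
}

#' Pool layer outputs into a patient vector
#'
#' The patient vector is the token-wise mean (over all content positions —
#' sequences are variable-length, so no padding is present) of the average of
#' the first and final layer outputs: `mean_t (H_first[t, ] + H_final[t, ]) / 2`.
#'
#' @param outputs A `layer_outputs` from [embed_sequence()] (or a plain list
#'   of `T x d` matrices, `H0` first).
#' @param first Index of the "first" layer: 1 = first encoder layer
#'   (default), 0 = embedding output.
#' @return Numeric vector of length `d_model`.
#' @export
pool_patient_vector <- function(outputs, first = 1L) {
  hs <- unclass(outputs)
  L <- length(hs) - 1L
  if (first > L) abort("`first` exceeds the number of encoder layers")
  H_first <- hs[[first + 1L]]
  H_final <- hs[[L + 1L]]
  if (nrow(H_final) == 0) abort("cannot pool an empty sequence")
  colMeans((H_first + H_final) / 2)
}

pool_first_index <- function(config) {
  if (config$pool_first == "embedding") 0L else 1L
}

#' InfoNCE contrastive loss
#'
#' With aligned batches of anchor and positive vectors (row i of `positives`
#' is the positive view of row i of `anchors`) and cosine similarity
#' `sim`, the loss is
#' `-(1/N) * sum_i log( exp(sim(a_i, p_i)/tau) / sum_j exp(sim(a_i, p_j)/tau) )`.
#' Equals `log N` exactly when all pairwise similarities are equal.
#'
#' @param anchors,positives Numeric matrices `N x d`, `N >= 2`.
#' @param tau Temperature (> 0).
#' @return Scalar loss.
#' @export
contrastive_loss <- function(anchors, positives, tau = 0.05) {
  info_nce(anchors, positives, tau)$loss
}

# loss + gradients wrt the raw (unnormalised) anchor and positive matrices
info_nce <- function(anchors, positives, tau) {
  A <- as.matrix(anchors); P <- as.matrix(positives)
  N <- nrow(A)
  if (N < 2) abort("contrastive loss needs a batch of at least 2 pairs")
  if (!all(dim(A) == dim(P))) abort("anchor and positive batches must align")
  if (tau <= 0) abort("`tau` must be > 0")
  na <- sqrt(rowSums(A^2)); np <- sqrt(rowSums(P^2))
  if (any(na == 0) || any(np == 0)) abort("cosine similarity undefined for zero-norm vectors")
  Ah <- A / na; Ph <- P / np
  S <- (Ah %*% t(Ph)) / tau
  m <- apply(S, 1, max)
  lse <- m + log(rowSums(exp(S - m)))
  loss <- mean(lse - diag(S))
  soft <- exp(S - lse)                      # row-wise softmax
  dS <- (soft - diag(N)) / N                # d loss / d S
  dAh <- (dS %*% Ph) / tau
  dPh <- (t(dS) %*% Ah) / tau
  # back through row normalisation x -> x / ||x||
  dA <- (dAh - Ah * rowSums(Ah * dAh)) / na
  dP <- (dPh - Ph * rowSums(Ph * dPh)) / np
  list(loss = loss, dA = dA, dP = dP)
}

#' Build a positive pair of patient vectors from one sequence
#'
#' Two stochastic "views" of the same patient history, encoded and pooled.
#' `"dropout-twin"` encodes the sequence twice under independent dropout
#' masks (requires `dropout > 0`); `"span-mask"` replaces
#' `floor(mask_rate * n_events + 0.5)` event tokens (never the CLS token)
#' with UNK independently in each view and encodes deterministically.
#'
#' @param seq A `token_sequence`.
#' @param model An `hf_encoder`.
#' @param mode Pair-construction mode (default from the model's config).
#' @param mask_rate Span-mask rate (default from the config).
#' @return List with vectors `anchor` and `positive`.
#' @export
make_positive_pair <- function(seq, model, mode = NULL, mask_rate = NULL) {
  cfg <- model$config
  mode <- mode %||% cfg$pair_mode
  mask_rate <- mask_rate %||% cfg$mask_rate
  first <- pool_first_index(cfg)
  if (mode == "dropout-twin") {
    if (cfg$dropout <= 0) {
      abort("dropout-twin positives need dropout > 0 (views would be identical)")
    }
    f1 <- encoder_forward(model, seq, train = TRUE)
    f2 <- encoder_forward(model, seq, train = TRUE)
  } else if (mode == "span-mask") {
    f1 <- encoder_forward(model, span_mask(seq, mask_rate), train = FALSE)
    f2 <- encoder_forward(model, span_mask(seq, mask_rate), train = FALSE)
  } else abort("unknown pair mode")
  list(anchor = pool_patient_vector(structure(f1$layers, class = "layer_outputs"), first),
       positive = pool_patient_vector(structure(f2$layers, class = "layer_outputs"), first),
       forwards = list(f1, f2))
}

# replace a fixed count of event tokens (positions 2..T) with UNK
span_mask <- function(seq, rate) {
  n_events <- length(seq$token_ids) - 1L
  n_mask <- floor(rate * n_events + 0.5)
  if (n_mask > 0) {
    pos <- 1L + sample.int(n_events, n_mask)
    seq$token_ids[pos] <- RESERVED_TOKENS[["UNK"]]
  }
  seq
}

#' Embed a cohort of token sequences into patient vectors
#'
#' Deterministic inference-mode encoding and first/final-layer pooling of
#' every sequence.
#'
#' @param seqs Named list of `token_sequence`s (from [tokenise_cohort()]).
#' @param model An `hf_encoder`.
#' @return A `patient_vectors` object with tag `"transformer"`.
#' @export
embed_cohort <- function(seqs, model) {
  stopifnot(inherits(model, "hf_encoder"))
  first <- pool_first_index(model$config)
  m <- matrix(0, length(seqs), model$config$d_model)
  for (i in seq_along(seqs)) {
    f <- encoder_forward(model, seqs[[i]], train = FALSE)
    m[i, ] <- pool_patient_vector(structure(f$layers, class = "layer_outputs"), first)
  }
  new_patient_vectors(m, vapply(seqs, `[[`, character(1), "patient_id"),
                      tag = "transformer")
}

#' Save / load an encoder checkpoint
#'
#' The checkpoint is a self-describing JSON file holding the configuration,
#' embedding-table dimensions and all weights.
#'
#' @param model An `hf_encoder`.
#' @param path File path.
#' @return `save_encoder` returns the path invisibly; `load_encoder` the
#'   restored model.
#' @export
save_encoder <- function(model, path) {
  payload <- list(
    config = unclass(model$config),
    dims = model$dims,
    trained = isTRUE(model$trained),
    log = if (!is.null(model$log)) as.list(model$log),
    params = rapply(model$params, function(m) {
      if (is.matrix(m)) list(dim = dim(m), data = as.vector(m)) else list(dim = length(m), data = m)
    }, how = "list")
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_encoder
#' @export
load_encoder <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = FALSE)
  cfg <- do.call(encoder_config, payload$config)
  rebuild <- function(x) {
    if (is.list(x) && identical(sort(names(x)), c("data", "dim"))) {
      dims <- unlist(x$dim)
      vals <- as.numeric(unlist(x$data))
      if (length(dims) == 2) matrix(vals, dims[1], dims[2]) else vals
    } else lapply(x, rebuild)
  }
  structure(list(params = rebuild(payload$params),
                 config = cfg,
                 dims = lapply(payload$dims, as.integer),
                 trained = isTRUE(payload$trained),
                 log = if (!is.null(payload$log))
                   tibble(epoch = as.integer(unlist(payload$log$epoch)),
                          mean_loss = as.numeric(unlist(payload$log$mean_loss)))),
            class = "hf_encoder")
}
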