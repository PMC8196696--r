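# LSTM sequence classifier, implemented directly from the gate
# recurrences:
#   f_t = sigma(Wxf x_t + Whf h_{t-1} + bf)
#   i_t = sigma(Wxi x_t + Whi h_{t-1} + bi)
#   o_t = sigma(Wxo x_t + Who h_{t-1} + bo)
#   g_t = tanh (Wxg x_t + Whg h_{t-1} + bg)
#   c_t = f_t (.) c_{t-1} + i_t (.) g_t
#   h_t = o_t (.) tanh(c_t)
# with a single logistic unit on the final unmasked hidden state as the
# classification head. Training is full backpropagation through time
# with mini-batch gradient descent and global gradient-norm clipping.

sigmoid_ <- function(x) 1 / (1 + exp(-x))

#' Initialize LSTM parameters
#'
#' All weights and biases drawn uniform on `(-s, s)` with
#' `s = 1/sqrt(H)` by default.
#'
#' The forget-gate bias starts at `forget_bias` (default 1) so the cell
#' state initially retains information across the sequence -- the
#' standard remedy for early forgetting when an informative event occurs
#' long before the sequence ends.
#'
#' @param input_size Input dimension D (20 for the take-sequence layout).
#' @param hidden_size Hidden dimension H.
#' @param seed Integer seed.
#' @param init_scale Half-width of the uniform initialization.
#' @param forget_bias Constant added to the forget-gate bias at init.
#' @return An [LSTMModel-class].
#' @export
lstmInit <- function(input_size = 20L, hidden_size = 16L, seed = 1L,
                     init_scale = 1 / sqrt(hidden_size), forget_bias = 1) {
  D <- as.integer(input_size); H <- as.integer(hidden_size)
  with_seed_(seed, {
    u <- function(n) runif(n, -init_scale, init_scale)
    p <- list()
    for (g in c("f", "i", "o", "g")) {
      p[[paste0("Wx", g)]] <- matrix(u(H * D), H, D)
      p[[paste0("Wh", g)]] <- matrix(u(H * H), H, H)
      p[[paste0("b", g)]] <- u(H)
    }
    p$bf <- p$bf + forget_bias
    p$w_out <- u(H)
    p$b_out <- u(1)
    new("LSTMModel", inputSize = D, hiddenSize = H, params = p,
        history = numeric(0))
  })
}

#' One LSTM step
#'
#' Applies the four-gate recurrence to a single input vector and the
#' previous hidden/cell state.
#'
#' @param x_t Input vector (length D).
#' @param h_prev,c_prev Previous hidden and cell state (length H).
#' @param params Parameter list (as in an [LSTMModel-class]'s `params`
#'   slot) or an `LSTMModel`.
#' @return List with `h` and `c` (each length H), plus the gate
#'   activations `f`, `i`, `o`, `g`.
#' @examples
#' m <- lstmInit(3, 2, seed = 1)
#' lstmStep(c(1, 0, -1), rep(0, 2), rep(0, 2), m)
#' @export
lstmStep <- function(x_t, h_prev, c_prev, params) {
  p <- if (is(params, "LSTMModel")) params@params else params
  H <- length(p$bf)
  if (length(x_t) != ncol(p$Wxf) || length(h_prev) != H || length(c_prev) != H) {
    stop("shape mismatch in lstmStep", call. = FALSE)
  }
  f <- sigmoid_(as.numeric(p$Wxf %*% x_t + p$Whf %*% h_prev) + p$bf)
  i <- sigmoid_(as.numeric(p$Wxi %*% x_t + p$Whi %*% h_prev) + p$bi)
  o <- sigmoid_(as.numeric(p$Wxo %*% x_t + p$Who %*% h_prev) + p$bo)
  g <- tanh(as.numeric(p$Wxg %*% x_t + p$Whg %*% h_prev) + p$bg)
  c_t <- f * c_prev + i * g
  h_t <- o * tanh(c_t)
  list(h = h_t, c = c_t, f = f, i = i, o = o, g = g)
}

#' Probability of the medication class for a take sequence
#'
#' Runs the recurrence over the sequence's real (unmasked) frames with
#' zero initial state and applies the logistic head to the final hidden
#' state: `sigma(w_out . h_last + b_out)`. Padding rows are skipped, so
#' appending padding never changes the output.
#'
#' @param seq A [TakeSequence-class] (or a plain `T x D` matrix, all rows
#'   real).
#' @param model An [LSTMModel-class].
#' @return Probability in `(0, 1)`.
#' @export
forwardSequence <- function(seq, model) {
  if (is(seq, "TakeSequence")) {
    X <- seq@channels[seq@mask, , drop = FALSE]
  } else {
    X <- as.matrix(seq)
  }
  if (ncol(X) != model@inputSize) {
    stop("sequence channel count does not match the model input size",
         call. = FALSE)
  }
  p <- model@params
  H <- model@hiddenSize
  h <- numeric(H); cc <- numeric(H)
  for (t in seq_len(nrow(X))) {
    st <- lstmStep(X[t, ], h, cc, p)
    h <- st$h; cc <- st$c
  }
  as.numeric(sigmoid_(sum(p$w_out * h) + p$b_out))
}

# ---- batched forward/backward over N sequences (internal) -------------

# Xl: list over t of D x N input matrices; M: T x N mask (1/0)
lstmBatchForward_ <- function(p, Xl, M) {
  T_len <- length(Xl); N <- ncol(Xl[[1]]); H <- length(p$bf)
  h <- matrix(0, H, N); cc <- matrix(0, H, N)
  cache <- vector("list", T_len)
  for (t in seq_len(T_len)) {
    x <- Xl[[t]]
    m <- matrix(M[t, ], H, N, byrow = TRUE)
    af <- p$Wxf %*% x + p$Whf %*% h + p$bf
    ai <- p$Wxi %*% x + p$Whi %*% h + p$bi
    ao <- p$Wxo %*% x + p$Who %*% h + p$bo
    ag <- p$Wxg %*% x + p$Whg %*% h + p$bg
    f <- sigmoid_(af); i <- sigmoid_(ai); o <- sigmoid_(ao); g <- tanh(ag)
    c_cand <- f * cc + i * g
    tc <- tanh(c_cand)
    h_cand <- o * tc
    h_new <- h_cand * m + h * (1 - m)
    c_new <- c_cand * m + cc * (1 - m)
    cache[[t]] <- list(x = x, h_prev = h, c_prev = cc, f = f, i = i, o = o,
                       g = g, tc = tc, m = m)
    h <- h_new; cc <- c_new
  }
  logit <- as.numeric(crossprod(p$w_out, h)) + p$b_out
  list(prob = sigmoid_(logit), h_last = h, cache = cache)
}

zeroGrads_ <- function(p) lapply(p, function(x) x * 0)

# mean binary cross-entropy loss and its gradients wrt all parameters
lstmLossGrad_ <- function(p, Xl, M, y) {
  fw <- lstmBatchForward_(p, Xl, M)
  prob <- fw$prob
  N <- length(y)
  eps <- 1e-12
  loss <- -mean(y * log(prob + eps) + (1 - y) * log(1 - prob + eps))
  gr <- zeroGrads_(p)
  dlogit <- (prob - y) / N
  gr$w_out <- as.numeric(fw$h_last %*% dlogit)
  gr$b_out <- sum(dlogit)
  H <- length(p$bf)
  dH <- p$w_out %o% dlogit
  dC <- matrix(0, H, ncol(dH))
  for (t in rev(seq_along(fw$cache))) {
    cc <- fw$cache[[t]]
    dh_cand <- dH * cc$m
    dh_skip <- dH * (1 - cc$m)
    dc_cand <- dC * cc$m + dh_cand * cc$o * (1 - cc$tc^2)
    dC <- dC * (1 - cc$m) + dc_cand * cc$f
    do_ <- dh_cand * cc$tc
    df <- dc_cand * cc$c_prev
    di <- dc_cand * cc$g
    dg <- dc_cand * cc$i
    da_f <- df * cc$f * (1 - cc$f)
    da_i <- di * cc$i * (1 - cc$i)
    da_o <- do_ * cc$o * (1 - cc$o)
    da_g <- dg * (1 - cc$g^2)
    gr$Wxf <- gr$Wxf + tcrossprod(da_f, cc$x)
    gr$Wxi <- gr$Wxi + tcrossprod(da_i, cc$x)
    gr$Wxo <- gr$Wxo + tcrossprod(da_o, cc$x)
    gr$Wxg <- gr$Wxg + tcrossprod(da_g, cc$x)
    gr$Whf <- gr$Whf + tcrossprod(da_f, cc$h_prev)
    gr$Whi <- gr$Whi + tcrossprod(da_i, cc$h_prev)
    gr$Who <- gr$Who + tcrossprod(da_o, cc$h_prev)
    gr$Whg <- gr$Whg + tcrossprod(da_g, cc$h_prev)
    gr$bf <- gr$bf + rowSums(da_f)
    gr$bi <- gr$bi + rowSums(da_i)
    gr$bo <- gr$bo + rowSums(da_o)
    gr$bg <- gr$bg + rowSums(da_g)
    dH <- dh_skip + crossprod(p$Whf, da_f) + crossprod(p$Whi, da_i) +
      crossprod(p$Who, da_o) + crossprod(p$Whg, da_g)
  }
  list(loss = loss, grads = gr, prob = prob)
}

gradNorm_ <- function(gr) sqrt(sum(vapply(gr, function(x) sum(x^2), numeric(1))))

# stack TakeSequences into batched inputs (list over t of D x N, mask T x N)
stackSequences_ <- function(seqs) {
  T_len <- nrow(seqs[[1]]@channels)
  D <- ncol(seqs[[1]]@channels)
  N <- length(seqs)
  Xl <- lapply(seq_len(T_len), function(t) {
    m <- matrix(0, D, N)
    for (n in seq_len(N)) m[, n] <- seqs[[n]]@channels[t, ]
    m
  })
  M <- matrix(0, T_len, N)
  for (n in seq_len(N)) M[, n] <- as.numeric(seqs[[n]]@mask)
  list(Xl = Xl, M = M)
}

#' Train the LSTM sequence classifier
#'
#' Minimizes mean binary cross-entropy over the training sequences by
#' mini-batch gradient descent through the full unrolled recurrence
#' (BPTT), with global gradient-norm clipping. Deterministic given the
#' seed.
#'
#' @param seqs List of labeled [TakeSequence-class] objects (both classes
#'   must be present).
#' @param config List of training tunables: `hidden` (default 16),
#'   `epochs` (200), `lr` (0.05), `batch_size` (32), `clip` (5),
#'   `init_scale` (`1/sqrt(hidden)`), `seed` (1).
#' @return An [LSTMModel-class] with the per-epoch loss history in its
#'   `history` slot.
#' @export
trainActionClassifier <- function(seqs, config = list()) {
  cfg <- modifyList(list(hidden = 16L, epochs = 200L, lr = 0.05,
                         batch_size = 32L, clip = 5, init_scale = NULL,
                         forget_bias = 1, seed = 1L), config)
  labels <- vapply(seqs, seqLabel, character(1))
  if (any(is.na(labels))) stop("all training sequences need labels", call. = FALSE)
  y <- as.numeric(labels == "medication")
  if (length(unique(y)) < 2L) {
    stop("training data must contain both classes", call. = FALSE)
  }
  D <- ncol(seqs[[1]]@channels)
  H <- as.integer(cfg$hidden)
  scale <- if (is.null(cfg$init_scale)) 1 / sqrt(H) else cfg$init_scale
  model <- lstmInit(D, H, seed = cfg$seed, init_scale = scale,
                    forget_bias = cfg$forget_bias)
  p <- model@params
  st <- stackSequences_(seqs)
  N <- length(seqs)
  history <- numeric(cfg$epochs)
  with_seed_(cfg$seed, {
    for (ep in seq_len(cfg$epochs)) {
      ord <- sample.int(N)
      batches <- split(ord, ceiling(seq_along(ord) / cfg$batch_size))
      ep_loss <- 0
      for (bt in batches) {
        Xb <- lapply(st$Xl, function(x) x[, bt, drop = FALSE])
        Mb <- st$M[, bt, drop = FALSE]
        lg <- lstmLossGrad_(p, Xb, Mb, y[bt])
        gn <- gradNorm_(lg$grads)
        sc <- if (gn > cfg$clip) cfg$clip / gn else 1
        for (nm in names(p)) p[[nm]] <- p[[nm]] - cfg$lr * sc * lg$grads[[nm]]
        ep_loss <- ep_loss + lg$loss * length(bt)
      }
      history[ep] <- ep_loss / N
    }
  })
  new("LSTMModel", inputSize = as.integer(D), hiddenSize = H, params = p,
      history = history)
}

#' Classify take sequences with a trained LSTM
#'
#' @param model An [LSTMModel-class].
#' @param seqs List of [TakeSequence-class] objects.
#' @return Data frame with `episode_id`, `score` (medication
#'   probability) and `label` (`"medication"` iff score > 0.5).
#' @export
classifySequences <- function(model, seqs) {
  scores <- vapply(seqs, forwardSequence, numeric(1), model = model)
  data.frame(episode_id = vapply(seqs, function(s) s@episodeId, character(1)),
             score = scores,
             label = ifelse(scores > 0.5, "medication", "non_medication"),
             stringsAsFactors = FALSE)
}

setMethod("show", "LSTMModel", function(object) {
  cat(sprintf("LSTMModel: D=%d, H=%d%s\n", object@inputSize,
              object@hiddenSize,
              if (length(object@history))
                sprintf(", trained %d epochs (final loss %.4f)",
                        length(object@history), tail(object@history, 1))
              else " (untrained)"))
})
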