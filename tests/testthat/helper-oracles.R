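# Independent oracles used by unit and acceptance tests. These are
# deliberately naive re-implementations (pixel enumeration, straight-line
# recurrences, explicit staircase construction) kept separate from the
# package's own code paths.

# IoU by brute-force pixel membership under the half-open convention
oracleIoU <- function(a, b) {
  lim_x <- max(a$x_max, b$x_max)
  lim_y <- max(a$y_max, b$y_max)
  px <- expand.grid(x = seq_len(lim_x) - 1L, y = seq_len(lim_y) - 1L)
  in_a <- px$x >= a$x_min & px$x < a$x_max & px$y >= a$y_min & px$y < a$y_max
  in_b <- px$x >= b$x_min & px$x < b$x_max & px$y >= b$y_min & px$y < b$y_max
  if (!any(in_a | in_b)) return(0)
  sum(in_a & in_b) / sum(in_a | in_b)
}

# average precision by explicit greedy matching and explicit
# precision-envelope staircase (max over suffix computed by a loop)
oracleAP <- function(dets, gts, category, iou_min = 0.5) {
  d <- dets[dets$category == category, , drop = FALSE]
  g <- gts[gts$category == category, , drop = FALSE]
  if (nrow(g) == 0L) return(0)
  if (nrow(d) == 0L) return(0)
  d <- d[order(-d$score, d$frame, d$x_min, d$y_min), , drop = FALSE]
  used <- rep(FALSE, nrow(g))
  is_tp <- rep(FALSE, nrow(d))
  for (i in seq_len(nrow(d))) {
    best_iou <- -1; best_j <- 0L
    for (j in seq_len(nrow(g))) {
      if (g$frame[j] != d$frame[i] || used[j]) next
      v <- oracleIoU(d[i, ], g[j, ])
      if (v >= iou_min && v > best_iou) { best_iou <- v; best_j <- j }
    }
    if (best_j > 0L) { used[best_j] <- TRUE; is_tp[i] <- TRUE }
  }
  tp <- 0; fp <- 0
  rec <- numeric(nrow(d)); prec <- numeric(nrow(d))
  for (i in seq_len(nrow(d))) {
    if (is_tp[i]) tp <- tp + 1 else fp <- fp + 1
    rec[i] <- tp / nrow(g)
    prec[i] <- tp / (tp + fp)
  }
  ap <- 0; r_prev <- 0
  for (i in seq_len(nrow(d))) {
    p_env <- 0
    for (j in i:nrow(d)) p_env <- max(p_env, prec[j])
    ap <- ap + (rec[i] - r_prev) * p_env
    r_prev <- rec[i]
  }
  ap
}

# straight-line transcription of the six LSTM gate equations
oracleLstmStep <- function(x, h_prev, c_prev, p) {
  sg <- function(z) 1 / (1 + exp(-z))
  f <- sg(p$Wxf %*% x + p$Whf %*% h_prev + p$bf)
  i <- sg(p$Wxi %*% x + p$Whi %*% h_prev + p$bi)
  o <- sg(p$Wxo %*% x + p$Who %*% h_prev + p$bo)
  g <- tanh(p$Wxg %*% x + p$Whg %*% h_prev + p$bg)
  ct <- f * c_prev + i * g
  ht <- o * tanh(ct)
  list(h = as.numeric(ht), c = as.numeric(ct))
}

# random small detection/ground-truth instance generator for AP fuzzing
randomAPInstance <- function() {
  n_gt <- sample(0:5, 1)
  n_det <- sample(1:10, 1)
  mkbox <- function(n) {
    x0 <- sample(0:20, n, replace = TRUE)
    y0 <- sample(0:20, n, replace = TRUE)
    data.frame(x_min = x0, y_min = y0,
               x_max = x0 + sample(2:12, n, replace = TRUE),
               y_max = y0 + sample(2:12, n, replace = TRUE))
  }
  gts <- cbind(data.frame(frame = sample(0:2, n_gt, replace = TRUE),
                          category = rep("pill", n_gt)), mkbox(n_gt))
  dets <- cbind(data.frame(frame = sample(0:2, n_det, replace = TRUE),
                           category = rep("pill", n_det)), mkbox(n_det))
  dets$score <- round(runif(n_det), 3)
  list(dets = dets, gts = gts)
}
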