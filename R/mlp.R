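# Minimal fully-connected network used by the MOREL-DNN learner: one
# hidden layer with ReLU activation and he-uniform initialisation, linear
# output layer, squared-error loss minimised by Adam on shuffled
# mini-batches. Deterministic under a fixed seed.

he_uniform <- function(n_in, n_out) {
  limit <- sqrt(6 / n_in)
  array(stats::runif(n_in * n_out, -limit, limit), dim = c(n_in, n_out))
}

mlp_fit <- function(x, y, hidden, epochs = 100L, batch_size = 256L,
                    learning_rate = 1e-3, seed = 1L) {
  n <- nrow(x); p <- ncol(x); q <- ncol(y)
  with_seed(seed, {
    w1 <- he_uniform(p, hidden); b1 <- numeric(hidden)
    w2 <- he_uniform(hidden, q); b2 <- numeric(q)
    adam <- list()
    for (nm in c("w1", "b1", "w2", "b2"))
      adam[[nm]] <- list(m = 0, v = 0)
    beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
    t_step <- 0L
    batch_size <- min(batch_size, n)
    for (ep in seq_len(epochs)) {
      perm <- sample.int(n)
      for (start in seq(1L, n, by = batch_size)) {
        idx <- perm[start:min(start + batch_size - 1L, n)]
        xb <- x[idx, , drop = FALSE]
        yb <- y[idx, , drop = FALSE]
        a1 <- sweep(xb %*% w1, 2L, b1, `+`)
        h <- a1 * (a1 > 0)
        out <- sweep(h %*% w2, 2L, b2, `+`)
        # d(mean squared error)/d(out)
        g_out <- 2 * (out - yb) / (length(idx) * q)
        g_w2 <- crossprod(h, g_out)
        g_b2 <- colSums(g_out)
        g_h <- g_out %*% t(w2)
        g_a1 <- g_h * (a1 > 0)
        g_w1 <- crossprod(xb, g_a1)
        g_b1 <- colSums(g_a1)
        t_step <- t_step + 1L
        grads <- list(w1 = g_w1, b1 = g_b1, w2 = g_w2, b2 = g_b2)
        params <- list(w1 = w1, b1 = b1, w2 = w2, b2 = b2)
        for (nm in names(grads)) {
          st <- adam[[nm]]
          st$m <- beta1 * st$m + (1 - beta1) * grads[[nm]]
          st$v <- beta2 * st$v + (1 - beta2) * grads[[nm]]^2
          mhat <- st$m / (1 - beta1^t_step)
          vhat <- st$v / (1 - beta2^t_step)
          params[[nm]] <- params[[nm]] -
            learning_rate * mhat / (sqrt(vhat) + eps)
          adam[[nm]] <- st
        }
        w1 <- params$w1; b1 <- params$b1
        w2 <- params$w2; b2 <- params$b2
      }
    }
    list(w1 = w1, b1 = b1, w2 = w2, b2 = b2, hidden = hidden)
  })
}

mlp_predict <- function(model, x) {
  a1 <- sweep(x %*% model$w1, 2L, model$b1, `+`)
  h <- a1 * (a1 > 0)
  sweep(h %*% model$w2, 2L, model$b2, `+`)
}
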