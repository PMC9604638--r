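# Thin R wrappers around the compiled network. The architecture is a small
# fully connected net -- two hidden ReLU layers (default 16, 8) and a
# sigmoid output -- trained with minibatch Adam on binary cross-entropy,
# with early stopping on validation loss. Weight initialization and epoch
# shuffles come from R's RNG, so results are reproducible under set.seed().

nn_init <- function(d_in, hidden = c(16, 8)) {
  stopifnot(length(hidden) == 2)
  he <- function(n_in, n_out) {
    matrix(stats::rnorm(n_in * n_out, 0, sqrt(2 / n_in)), n_in, n_out)
  }
  list(
    W1 = he(d_in, hidden[1]), b1 = rep(0, hidden[1]),
    W2 = he(hidden[1], hidden[2]), b2 = rep(0, hidden[2]),
    W3 = he(hidden[2], 1), b3 = 0
  )
}

nn_train <- function(weights, X, y, Xval, yval, lr = 1e-3, batch = 32,
                     epochs = 200, patience = 20, l2 = 1e-4,
                     freeze_first = FALSE) {
  X <- as.matrix(X)
  Xval <- as.matrix(Xval)
  if (epochs == 0) {
    p <- nn_prob(weights, Xval)
    return(list(
      weights = weights, val_loss = nn_bce(p, yval),
      train_history = numeric(0), val_history = numeric(0), epochs_run = 0L
    ))
  }
  n <- nrow(X)
  shuffles <- t(vapply(seq_len(epochs), function(e) sample.int(n), integer(n)))
  cpp_nn_train(
    weights, X, as.numeric(y), Xval, as.numeric(yval),
    shuffles, lr, as.integer(batch), as.integer(patience), l2, freeze_first
  )
}

nn_prob <- function(weights, X) {
  as.numeric(cpp_nn_forward_prob(weights, as.matrix(X)))
}

nn_hidden_act <- function(weights, X) {
  cpp_nn_hidden(weights, as.matrix(X))
}

nn_bce <- function(p, y) {
  q <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  -mean(y * log(q) + (1 - y) * log(1 - q))
}
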