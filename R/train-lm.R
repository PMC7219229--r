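# Levenberg-Marquardt training with early stopping.
#
# LM interpolates between Gauss-Newton and gradient descent through the
# damping parameter mu: each epoch solves (J'J + mu I) delta = J'r on the
# training residuals r = b - a, accepts the step if the training loss
# decreases (mu shrinks) and otherwise rejects and raises mu. Training stops
# at the epoch budget, when the loss gradient is essentially zero, or when the
# validation loss has not improved for `patience` consecutive epochs; the
# weights with the best validation loss are returned.

#' Training configuration
#'
#' Defaults mirror the study regime: at most 1000 epochs, gradient tolerance
#' 1e-7, a 30% validation split, and early stopping after 6 epochs without
#' validation improvement.
#'
#' @param loss `"mse"` (default), `"msereg"` or `"sse"`.
#' @param reg_ratio gamma for MSEREG, in (0, 1].
#' @param max_epochs epoch budget (>= 1).
#' @param grad_tol stop when `max|d loss / d theta|` falls below this.
#' @param val_fraction proportion of rows set aside for validation, in (0, 1).
#' @param patience consecutive epochs without validation improvement tolerated.
#' @param seed integer seed (weight init and validation split).
#' @param lm_mu0 initial damping.
#' @param lm_mu_factor damping multiplier/divisor on reject/accept.
#' @return an object of class `train_config`.
#' @export
train_config <- function(loss = "mse", reg_ratio = 0.9, max_epochs = 1000,
                         grad_tol = 1e-7, val_fraction = 0.30, patience = 6,
                         seed = 1, lm_mu0 = 1e-3, lm_mu_factor = 10) {
  loss <- match.arg(tolower(loss), c("mse", "msereg", "sse"))
  if (max_epochs < 1) stop("max_epochs must be at least 1")
  if (!(val_fraction > 0 && val_fraction < 1))
    stop("val_fraction must lie strictly between 0 and 1")
  stopifnot(reg_ratio > 0, reg_ratio <= 1, grad_tol >= 0, patience >= 1,
            lm_mu0 > 0, lm_mu_factor > 1)
  structure(list(loss = loss, reg_ratio = reg_ratio,
                 max_epochs = as.integer(max_epochs), grad_tol = grad_tol,
                 val_fraction = val_fraction, patience = as.integer(patience),
                 seed = as.integer(seed), lm_mu0 = lm_mu0,
                 lm_mu_factor = lm_mu_factor),
            class = "train_config")
}

replace_seed <- function(cfg, seed) { cfg$seed <- as.integer(seed); cfg }

# Forward pass retaining layer activations, then the n x p Jacobian of the
# network output w.r.t. all parameters, assembled layer-block by layer-block
# in flatten_params() order (W column-major, then b).
ann_jacobian <- function(model, X) {
  L <- length(model$layers)
  As <- vector("list", L + 1)
  As[[1]] <- X
  for (j in seq_len(L)) {
    l <- model$layers[[j]]
    As[[j + 1]] <- act_fn(l$act)(sweep(As[[j]] %*% t(l$w), 2, l$b, `+`))
  }
  a <- as.numeric(As[[L + 1]])
  D <- act_grad(model$layers[[L]]$act, As[[L + 1]]) # n x 1
  blocks <- vector("list", L)
  for (j in L:1) {
    out_j <- nrow(model$layers[[j]]$w)
    in_j <- ncol(model$layers[[j]]$w)
    Jw <- D[, rep(seq_len(out_j), times = in_j), drop = FALSE] *
      As[[j]][, rep(seq_len(in_j), each = out_j), drop = FALSE]
    blocks[[j]] <- cbind(Jw, D)
    if (j > 1) {
      D <- (D %*% model$layers[[j]]$w) *
        act_grad(model$layers[[j - 1]]$act, As[[j]])
    }
  }
  list(a = a, J = do.call(cbind, blocks))
}

loss_value <- function(targets, a, theta, cfg) {
  r2 <- (targets - a)^2
  switch(cfg$loss,
    mse = mean(r2),
    sse = sum(r2),
    msereg = cfg$reg_ratio * mean(r2) +
      (1 - cfg$reg_ratio) * mean(theta^2))
}

#' Train a network with Levenberg-Marquardt and early stopping
#'
#' @param topology topology label (e.g. `"FF 20 1"`); NARX labels train open
#'   loop on teacher-forced windows from [build_narx_windows()].
#' @param ws a `window_set` of training rows. A warning is issued when the set
#'   has fewer than 10 rows per model parameter.
#' @param cfg a [train_config()]. The validation split is a random row-level
#'   split, stratified by subject when `ws$groups` is present.
#' @param hidden_act hidden-layer activation.
#' @return list with `model` (best-validation-loss weights) and `log`
#'   (data.frame: epoch, mu, train loss, validation loss, accepted flag).
#'   Fully reproducible given `cfg$seed`.
#' @export
train_lm <- function(topology, ws, cfg = train_config(), hidden_act = "tanh") {
  stopifnot(inherits(ws, "window_set"), inherits(cfg, "train_config"))
  n <- nrow(ws$inputs)
  if (n < 4) stop("too few training windows")
  spec <- parse_topology(topology)
  n_exo <- if (spec$kind == "NARX" && !is.null(ws$feedback))
    ncol(ws$inputs) - ws$feedback else ncol(ws$inputs)
  model <- ann_init(topology, n_exo, seed = derive_seed(cfg$seed, "init"),
                    hidden_act = hidden_act,
                    feedback = if (!is.null(ws$feedback)) ws$feedback else 10L)
  p <- n_params(model)
  if (n < 10 * p)
    warning(sprintf("window set has %d rows for %d parameters (< 10 per parameter)",
                    n, p), call. = FALSE)

  # stratified validation split
  val_idx <- with_seed(derive_seed(cfg$seed, "valsplit"), {
    if (!is.null(ws$groups)) {
      unlist(lapply(split(seq_len(n), ws$groups), function(rows) {
        k <- round(cfg$val_fraction * length(rows))
        if (k > 0) sample(rows, k) else integer(0)
      }), use.names = FALSE)
    } else {
      k <- round(cfg$val_fraction * n)
      if (k > 0) sample(seq_len(n), k) else integer(0)
    }
  })
  tr_idx <- setdiff(seq_len(n), val_idx)
  Xtr <- ws$inputs[tr_idx, , drop = FALSE]; btr <- ws$targets[tr_idx]
  Xva <- ws$inputs[val_idx, , drop = FALSE]; bva <- ws$targets[val_idx]
  has_val <- length(val_idx) > 0
  M <- length(btr)

  theta <- flatten_params(model)
  a <- ann_predict(model, Xtr)
  cur_loss <- loss_value(btr, a, theta, cfg)
  if (!is.finite(cur_loss)) stop("non-finite initial loss; aborting")
  val_loss_of <- function(mod) {
    if (!has_val) return(NA_real_)
    loss_value(bva, ann_predict(mod, Xva), flatten_params(mod), cfg)
  }
  best_val <- val_loss_of(model)
  best_theta <- theta
  stall <- 0L
  mu <- cfg$lm_mu0
  log_rows <- list()

  for (epoch in seq_len(cfg$max_epochs)) {
    fj <- ann_jacobian(model, Xtr)
    r <- btr - fj$a
    G <- crossprod(fj$J)
    g <- crossprod(fj$J, r)[, 1]
    # gradient of the configured loss w.r.t. theta (sign aside)
    grad_scale <- switch(cfg$loss, mse = 2 / M, sse = 2,
                         msereg = 2 * cfg$reg_ratio / M)
    if (max(abs(grad_scale * g)) < cfg$grad_tol) break
    if (cfg$loss == "msereg") {
      lam <- (1 - cfg$reg_ratio) / cfg$reg_ratio * M / p
      G <- G + diag(lam, p)
      g <- g - lam * theta
    }
    accepted <- FALSE
    attempt_loss <- NA_real_
    while (mu <= 1e10) {
      Gd <- G
      diag(Gd) <- diag(Gd) + mu
      R <- tryCatch(chol(Gd), error = function(e) NULL)
      delta <- if (is.null(R)) NULL else
        backsolve(R, forwardsolve(t(R), g))
      if (!is.null(delta)) {
        cand_theta <- theta + delta
        cand_model <- unflatten_params(model, cand_theta)
        cand_a <- ann_predict(cand_model, Xtr)
        attempt_loss <- loss_value(btr, cand_a, cand_theta, cfg)
        if (is.finite(attempt_loss) && attempt_loss < cur_loss) {
          theta <- cand_theta; model <- cand_model; cur_loss <- attempt_loss
          mu <- max(mu / cfg$lm_mu_factor, 1e-12)
          accepted <- TRUE
          break
        }
      }
      mu <- mu * cfg$lm_mu_factor
    }
    vl <- val_loss_of(model)
    log_rows[[length(log_rows) + 1L]] <-
      data.frame(epoch = epoch, mu = mu, train_loss = cur_loss,
                 val_loss = vl, accepted = accepted)
    if (!accepted) break # damping exhausted: converged
    if (has_val) {
      if (is.na(best_val) || vl < best_val - 1e-15) {
        best_val <- vl; best_theta <- theta; stall <- 0L
      } else {
        stall <- stall + 1L
        if (stall >= cfg$patience) break
      }
    } else {
      best_theta <- theta
    }
  }
  final <- unflatten_params(model, if (has_val) best_theta else theta)
  list(model = final,
       log = if (length(log_rows)) do.call(rbind, log_rows) else
         data.frame(epoch = integer(0), mu = numeric(0),
                    train_loss = numeric(0), val_loss = numeric(0),
                    accepted = logical(0)))
}
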