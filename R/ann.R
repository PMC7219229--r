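# Shallow feed-forward networks: each neuron computes an affine combination of
# its inputs (weights plus bias) passed through its layer's activation; the
# single output neuron always uses the logistic sigmoid, so the network output
# is a beat probability in (0, 1).

ACTIVATIONS <- c("tanh", "logsig", "linear", "sigmoid")

act_fn <- function(name) {
  switch(name,
    tanh = tanh,
    logsig = ,
    sigmoid = function(z) 1 / (1 + exp(-z)),
    linear = identity,
    stop("unknown activation: ", name))
}

# derivative expressed through the activation value A
act_grad <- function(name, A) {
  switch(name,
    tanh = 1 - A^2,
    logsig = ,
    sigmoid = A * (1 - A),
    linear = array(1, dim(A)),
    stop("unknown activation: ", name))
}

# "FF 20 1" / "FF_20_1" / "NARX 10 1" -> kind + layer sizes (last must be 1,
# the sigmoid output neuron; earlier sizes are hidden layers).
parse_topology <- function(topology) {
  toks <- strsplit(trimws(gsub("[_-]", " ", topology)), "\\s+")[[1]]
  kind <- toupper(toks[1])
  if (!kind %in% c("FF", "NARX")) stop("unknown topology kind: ", toks[1])
  sizes <- suppressWarnings(as.integer(toks[-1]))
  if (length(sizes) < 1 || any(is.na(sizes)) || any(sizes < 1))
    stop("malformed topology: ", topology)
  if (sizes[length(sizes)] != 1)
    stop("final layer must have exactly 1 unit: ", topology)
  list(kind = kind, sizes = sizes)
}

#' Initialize a shallow ANN
#'
#' Weights are drawn symmetric-uniform scaled by layer fan-in
#' (`U(-1/sqrt(fan_in), 1/sqrt(fan_in))`), biases zero; fully reproducible
#' from the seed. Hidden layers use `hidden_act`; the output neuron is always
#' a sigmoid.
#'
#' @param topology label such as `"FF 20 1"` (hidden sizes then the single
#'   output unit) or `"NARX 10 1"`.
#' @param n_inputs input vector length (exogenous part only for NARX).
#' @param seed integer seed.
#' @param hidden_act hidden activation: `"tanh"` (default), `"logsig"` or
#'   `"linear"`.
#' @param feedback NARX feedback depth (ignored for FF).
#' @return an object of class `ann_model`.
#' @export
ann_init <- function(topology, n_inputs, seed = 1, hidden_act = "tanh",
                     feedback = 10L) {
  spec <- parse_topology(topology)
  hidden_act <- match.arg(hidden_act, c("tanh", "logsig", "linear"))
  n_in <- as.integer(n_inputs)
  if (spec$kind == "NARX") n_in <- n_in + as.integer(feedback)
  dims <- c(n_in, spec$sizes)
  layers <- with_seed(seed, {
    lapply(seq_along(spec$sizes), function(j) {
      fan_in <- dims[j]; fan_out <- dims[j + 1]
      s <- 1 / sqrt(fan_in)
      list(w = matrix(stats::runif(fan_out * fan_in, -s, s), fan_out, fan_in),
           b = numeric(fan_out),
           act = if (j == length(spec$sizes)) "sigmoid" else hidden_act)
    })
  })
  structure(list(layers = layers, topology = topology, kind = spec$kind,
                 n_inputs = as.integer(n_inputs),
                 feedback = if (spec$kind == "NARX") as.integer(feedback) else 0L),
            class = "ann_model")
}

#' @export
print.ann_model <- function(x, ...) {
  dims <- c(ncol(x$layers[[1]]$w), vapply(x$layers, function(l) nrow(l$w), 0L))
  cat(sprintf("<ann_model> %s: %s (%d parameters)\n", x$topology,
              paste(dims, collapse = " -> "), n_params(x)))
  invisible(x)
}

n_params <- function(model) {
  sum(vapply(model$layers, function(l) length(l$w) + length(l$b), 0))
}

#' Forward pass of the network
#'
#' `ann_forward` maps one input vector to the output probability;
#' `ann_predict` maps a matrix (or a `window_set`) row-wise.
#'
#' @param model an [ann_init()] model.
#' @param input numeric vector matching the model's first layer.
#' @return probability in (0, 1).
#' @export
ann_forward <- function(model, input) {
  stopifnot(inherits(model, "ann_model"))
  if (length(input) != ncol(model$layers[[1]]$w))
    stop(sprintf("input length %d does not match first layer width %d",
                 length(input), ncol(model$layers[[1]]$w)))
  as.numeric(ann_predict(model, matrix(input, nrow = 1)))
}

#' @rdname ann_forward
#' @param X numeric matrix of row inputs, or a `window_set`.
#' @return `ann_predict` returns a vector of probabilities.
#' @export
ann_predict <- function(model, X) {
  stopifnot(inherits(model, "ann_model"))
  if (inherits(X, "window_set")) X <- X$inputs
  if (!is.matrix(X)) X <- matrix(X, nrow = 1)
  if (ncol(X) != ncol(model$layers[[1]]$w))
    stop(sprintf("input width %d does not match first layer width %d",
                 ncol(X), ncol(model$layers[[1]]$w)))
  A <- X
  for (l in model$layers) {
    A <- act_fn(l$act)(sweep(A %*% t(l$w), 2, l$b, `+`))
  }
  as.numeric(A)
}

#' Training loss of a model on a window set
#'
#' `MSE = mean((b - a)^2)`, `SSE = sum((b - a)^2)`, and
#' `MSEREG = gamma * MSE + (1 - gamma) * mean(theta^2)` where `b` are targets,
#' `a` network outputs and `theta` all weights and biases.
#'
#' @param model an `ann_model`.
#' @param ws a `window_set` (non-empty).
#' @param loss one of `"mse"`, `"sse"`, `"msereg"`.
#' @param reg_ratio the `gamma` in MSEREG, in (0, 1].
#' @return scalar loss.
#' @export
ann_loss <- function(model, ws, loss = "mse", reg_ratio = 0.9) {
  stopifnot(inherits(ws, "window_set"))
  if (!nrow(ws$inputs)) stop("empty window set")
  loss <- match.arg(tolower(loss), c("mse", "sse", "msereg"))
  a <- ann_predict(model, ws)
  r2 <- (ws$targets - a)^2
  switch(loss,
    mse = mean(r2),
    sse = sum(r2),
    msereg = {
      stopifnot(reg_ratio > 0, reg_ratio <= 1)
      theta <- flatten_params(model)
      reg_ratio * mean(r2) + (1 - reg_ratio) * mean(theta^2)
    })
}

flatten_params <- function(model) {
  unlist(lapply(model$layers, function(l) c(as.vector(l$w), l$b)),
         use.names = FALSE)
}

unflatten_params <- function(model, theta) {
  pos <- 0L
  for (j in seq_along(model$layers)) {
    l <- model$layers[[j]]
    nw <- length(l$w); nb <- length(l$b)
    model$layers[[j]]$w <- matrix(theta[pos + seq_len(nw)], nrow(l$w), ncol(l$w))
    model$layers[[j]]$b <- theta[pos + nw + seq_len(nb)]
    pos <- pos + nw + nb
  }
  model
}

#' Save / load a model as decimal text
#'
#' Weights are serialized as JSON decimal text at full precision (17
#' significant digits), so a saved-then-loaded model reproduces its forward
#' pass bit-exactly.
#'
#' @param model an `ann_model`.
#' @param path file path.
#' @export
save_ann <- function(model, path) {
  stopifnot(inherits(model, "ann_model"))
  payload <- list(
    format = "radarbeat-ann-1",
    topology = model$topology, kind = model$kind,
    n_inputs = model$n_inputs, feedback = model$feedback,
    layers = lapply(model$layers, function(l)
      list(dim = dim(l$w), w = sprintf("%.17g", as.vector(l$w)),
           b = sprintf("%.17g", l$b), act = l$act)))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname save_ann
#' @return `load_ann` returns the restored `ann_model`.
#' @export
load_ann <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(p$format) || p$format != "radarbeat-ann-1")
    stop("not a radarbeat model file: ", path)
  layers <- lapply(seq_len(nrow_or_len(p$layers)), function(j) {
    l <- layer_entry(p$layers, j)
    list(w = matrix(as.double(l$w), l$dim[1], l$dim[2]),
         b = as.double(l$b), act = l$act)
  })
  structure(list(layers = layers, topology = p$topology, kind = p$kind,
                 n_inputs = as.integer(p$n_inputs),
                 feedback = as.integer(p$feedback)),
            class = "ann_model")
}

# jsonlite may simplify the layer list to a data.frame; handle both shapes
nrow_or_len <- function(x) if (is.data.frame(x)) nrow(x) else length(x)
layer_entry <- function(x, j) {
  if (is.data.frame(x))
    list(dim = unlist(x$dim[j]), w = unlist(x$w[j]), b = unlist(x$b[j]),
         act = unlist(x$act[j]))
  else x[[j]]
}

#' Single NARX step
#'
#' The input vector is the exogenous window concatenated with the previous
#' network outputs (oldest to newest); the rest is a plain forward pass.
#' Training is open loop (teacher-forced, see [build_narx_windows()]);
#' evaluation runs closed loop via [narx_predict()].
#'
#' @param model a NARX `ann_model`.
#' @param exogenous numeric vector of length `model$n_inputs`.
#' @param feedback numeric vector of the previous `model$feedback` outputs.
#' @return probability in (0, 1).
#' @export
narx_forward <- function(model, exogenous, feedback) {
  stopifnot(inherits(model, "ann_model"), model$kind == "NARX")
  if (length(exogenous) != model$n_inputs)
    stop("exogenous window length does not match the model")
  if (length(feedback) != model$feedback)
    stop(sprintf("feedback depth %d does not match the model's %d",
                 length(feedback), model$feedback))
  ann_forward(model, c(exogenous, feedback))
}

#' Closed-loop NARX prediction over a recording's windows
#'
#' Iterates [narx_forward()] across all causal windows, feeding the network's
#' own previous outputs back (zero-initialized buffer).
#'
#' @param model a NARX `ann_model`.
#' @param ws a `window_set` built with [build_windows()] (exogenous part only).
#' @return vector of probabilities, one per window row.
#' @export
narx_predict <- function(model, ws) {
  stopifnot(inherits(model, "ann_model"), model$kind == "NARX",
            inherits(ws, "window_set"))
  X <- ws$inputs
  if (ncol(X) != model$n_inputs)
    stop("window width does not match the model's exogenous input size")
  fb <- numeric(model$feedback)
  out <- numeric(nrow(X))
  for (k in seq_len(nrow(X))) {
    y <- ann_forward(model, c(X[k, ], fb))
    out[k] <- y
    fb <- c(fb[-1], y)
  }
  out
}
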