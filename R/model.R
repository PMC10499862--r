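#' Model architecture configuration
#'
#' Describes the encoder / (bidirectional) LSTM / decoder stack. The
#' encoder and decoder are per-residue feedforward maps; the recurrent
#' middle carries information along the sequence in both directions, so a
#' prediction at residue i can depend on every other residue. With
#' `use_lstm = FALSE` the recurrent middle is removed and the model
#' degenerates to a plain feedforward network acting on each residue
#' independently (the ablation variant).
#'
#' @param input_dim Feature width, 28 for the standard encoding.
#' @param encoder_widths Integer vector of encoder layer widths (may be
#'   empty for no encoder).
#' @param lstm_hidden Hidden state size per direction.
#' @param lstm_layers Number of stacked recurrent layers.
#' @param bidirectional Concatenate a forward and a backward pass?
#' @param decoder_widths Integer vector of decoder widths, ending at 1.
#' @param use_lstm Keep the recurrent middle?
#' @param activation `"tanh"` or `"relu"` for encoder/decoder hidden
#'   layers (the final decoder layer is linear).
#' @return A `model_config` object.
#' @export
model_config <- function(input_dim = 28L, encoder_widths = c(32L),
                         lstm_hidden = 32L, lstm_layers = 1L,
                         bidirectional = TRUE, decoder_widths = c(32L, 1L),
                         use_lstm = TRUE,
                         activation = c("tanh", "relu")) {
  activation <- match.arg(activation)
  widths <- c(encoder_widths, decoder_widths,
              if (use_lstm) c(lstm_hidden, lstm_layers))
  if (length(widths) && any(widths < 1))
    stop("all widths must be >= 1")
  if (decoder_widths[length(decoder_widths)] != 1)
    stop("decoder_widths must end at 1")
  structure(list(input_dim = as.integer(input_dim),
                 encoder_widths = as.integer(encoder_widths),
                 lstm_hidden = as.integer(lstm_hidden),
                 lstm_layers = as.integer(lstm_layers),
                 bidirectional = isTRUE(bidirectional),
                 decoder_widths = as.integer(decoder_widths),
                 use_lstm = isTRUE(use_lstm),
                 activation = activation),
            class = "model_config")
}

#' Training configuration
#'
#' @param seeds Integer vector of training seeds; the robustness protocol
#'   retrains once per seed (default four seeds).
#' @param max_epochs Maximum number of epochs.
#' @param batch_size Proteins per optimization step.
#' @param learning_rate Adam step size.
#' @param optimizer Only `"adam"` is implemented.
#' @param early_stop_patience Stop after this many epochs without a new
#'   validation-loss minimum.
#' @param b_mode Target mode the encodings were produced with.
#' @return A `train_config` object.
#' @export
train_config <- function(seeds = c(11L, 22L, 33L, 44L), max_epochs = 300L,
                         batch_size = 32L, learning_rate = 1e-3,
                         optimizer = "adam", early_stop_patience = 20L,
                         b_mode = c("normalized", "unnormalized")) {
  b_mode <- match.arg(b_mode)
  if (length(seeds) < 1L) stop("seeds must be nonempty")
  if (max_epochs < 1L) stop("max_epochs must be >= 1")
  structure(list(seeds = as.integer(seeds), max_epochs = as.integer(max_epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, optimizer = optimizer,
                 early_stop_patience = as.integer(early_stop_patience),
                 b_mode = b_mode),
            class = "train_config")
}

cfg_for_cpp <- function(config) {
  list(input_dim = config$input_dim,
       encoder_widths = as.integer(config$encoder_widths),
       use_lstm = config$use_lstm,
       lstm_hidden = config$lstm_hidden,
       lstm_layers = config$lstm_layers,
       bidirectional = config$bidirectional,
       decoder_widths = as.integer(config$decoder_widths),
       activation = config$activation)
}

#' Build a predictor with seeded initial weights
#'
#' Weight matrices are drawn uniformly from (-1/sqrt(fan_in),
#' +1/sqrt(fan_in)); biases start at zero except the LSTM forget-gate
#' block, which starts at 1 so early gradients flow along the sequence.
#' The same config and seed always produce bit-identical parameters.
#'
#' @param config A [model_config()].
#' @param seed Integer seed.
#' @return A `bf_predictor` with the flat parameter vector in `$params`.
#' @export
build_model <- function(config, seed = 1L) {
  shapes <- nn_shapes_cpp(cfg_for_cpp(config))
  params <- with_seed(seed, function() {
    unlist(lapply(shapes, function(s) {
      n <- s$rows * s$cols
      if (s$kind %in% c("enc_b", "dec_b")) return(rep(0, n))
      if (s$kind == "lstm_b") {
        h <- s$rows / 4L
        b <- rep(0, n)
        b[(h + 1):(2 * h)] <- 1  # forget gate
        return(b)
      }
      lim <- 1 / sqrt(s$cols)
      runif(n, -lim, lim)
    }))
  })
  structure(list(config = config, params = params, seed = as.integer(seed),
                 mask = NULL, b_mode = NULL),
            class = "bf_predictor")
}

#' @export
print.bf_predictor <- function(x, ...) {
  cat(sprintf("<bf_predictor> %s, %s params, seed %d\n",
              if (x$config$use_lstm) "encoder+biLSTM+decoder" else "feedforward",
              format(count_parameters(x), big.mark = ","), x$seed))
  invisible(x)
}

#' Count tunable parameters of a predictor
#'
#' Closed-form layer arithmetic: every dense layer contributes
#' fan_in x fan_out + fan_out, every recurrent layer and direction
#' contributes 4H x (fan_in + H + 1) for its four gate blocks. The count
#' is independent of sequence length N — weights are shared across
#' positions, which is what lets one instance handle any N.
#'
#' @param model A `bf_predictor` (or a `model_config`).
#' @return Integer parameter count.
#' @export
count_parameters <- function(model) {
  cfg <- if (inherits(model, "model_config")) model else model$config
  total <- 0
  fan <- cfg$input_dim
  for (w in cfg$encoder_widths) {
    total <- total + fan * w + w
    fan <- w
  }
  if (cfg$use_lstm) {
    dirs <- if (cfg$bidirectional) 2L else 1L
    h <- cfg$lstm_hidden
    lin <- fan
    for (l in seq_len(cfg$lstm_layers)) {
      total <- total + dirs * (4 * h * (lin + h + 1))
      lin <- h * dirs
    }
    fan <- h * dirs
  }
  for (w in cfg$decoder_widths) {
    total <- total + fan * w + w
    fan <- w
  }
  as.integer(total)
}

#' Predict per-residue B values for one encoded protein
#'
#' Runs the forward pass on an N x 28 feature matrix. With the recurrent
#' middle the output at residue i may depend on every row of the input;
#' the no-LSTM ablation is a per-row pure function. Inference is
#' deterministic.
#'
#' @param model A `bf_predictor`.
#' @param features Either an encoding list from [encode_protein()] or a
#'   bare N x `input_dim` matrix.
#' @return Numeric vector of N predictions (model scale).
#' @export
predict_protein <- function(model, features) {
  X <- if (is.list(features)) features$X else features
  if (!is.matrix(X) || ncol(X) != model$config$input_dim)
    stop("feature matrix width must equal input_dim (",
         model$config$input_dim, ")")
  as.numeric(nn_forward_cpp(model$params, cfg_for_cpp(model$config), X))
}

mse_loss_grad <- function(model, encodings) {
  nn_loss_grad_cpp(model$params, cfg_for_cpp(model$config),
                   lapply(encodings, `[[`, "X"),
                   lapply(encodings, `[[`, "y"))
}

#' Per-protein mean squared error of a prediction
#'
#' The training objective: the squared residuals averaged over the N
#' residues of one protein (and averaged over proteins in a batch during
#' training).
#'
#' @param predicted,actual Equal-length numeric vectors.
#' @return Scalar MSE.
#' @export
mse <- function(predicted, actual) {
  if (length(predicted) != length(actual)) stop("length mismatch")
  mean((predicted - actual)^2)
}

#' Train a predictor with Adam and early stopping
#'
#' Minimizes the per-protein mean squared error, averaged over the
#' proteins of each batch, on Z-scored (or scaled raw) targets. Proteins
#' are processed at their native lengths, so no residue position ever
#' contributes padding to the loss. The validation loss is recorded every
#' epoch; the returned weights are those of the best epoch (earliest
#' epoch wins ties). Fixed seed gives a reproducible history.
#'
#' @param config A [model_config()].
#' @param tc A [train_config()].
#' @param train_set,val_set Nonempty lists of encodings (see
#'   [encode_dataset()]), all produced with one mask and `tc$b_mode`.
#' @param seed Training seed; defaults to the first of `tc$seeds`.
#' @param verbose Print one line per epoch?
#' @return List with `model` (a `bf_predictor` carrying the best-epoch
#'   weights, the mask, and the target mode) and `history` (data.frame of
#'   per-epoch train/validation loss, plus `best_epoch` attribute).
#' @export
train_model <- function(config, tc, train_set, val_set,
                        seed = tc$seeds[[1L]], verbose = FALSE) {
  if (length(train_set) == 0L || length(val_set) == 0L)
    stop("training and validation manifests must be nonempty")
  if (tc$optimizer != "adam") stop("unsupported optimizer: ", tc$optimizer)
  model <- build_model(config, seed = seed)
  cpp_cfg <- cfg_for_cpp(config)
  Xtr <- lapply(train_set, `[[`, "X")
  ytr <- lapply(train_set, `[[`, "y")
  Xva <- lapply(val_set, `[[`, "X")
  yva <- lapply(val_set, `[[`, "y")

  theta <- model$params
  m <- v <- numeric(length(theta))
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  step <- 0L
  n_tr <- length(train_set)
  train_hist <- val_hist <- numeric(0)
  best_val <- Inf; best_theta <- theta; best_epoch <- 0L
  stale <- 0L

  for (epoch in seq_len(tc$max_epochs)) {
    ord <- with_seed(derive_seed(seed, epoch), function() sample.int(n_tr))
    batch_losses <- numeric(0)
    for (lo in seq(1L, n_tr, by = tc$batch_size)) {
      hi <- min(lo + tc$batch_size - 1L, n_tr)
      sel <- ord[lo:hi]
      lg <- nn_loss_grad_cpp(theta, cpp_cfg, Xtr[sel], ytr[sel])
      if (!is.finite(lg$loss))
        stop("training diverged: non-finite loss at epoch ", epoch)
      step <- step + 1L
      m <- b1 * m + (1 - b1) * lg$grad
      v <- b2 * v + (1 - b2) * lg$grad^2
      mhat <- m / (1 - b1^step)
      vhat <- v / (1 - b2^step)
      theta <- theta - tc$learning_rate * mhat / (sqrt(vhat) + eps)
      batch_losses <- c(batch_losses, lg$loss)
    }
    val_loss <- nn_loss_grad_cpp(theta, cpp_cfg, Xva, yva)$loss
    train_hist <- c(train_hist, mean(batch_losses))
    val_hist <- c(val_hist, val_loss)
    if (verbose)
      message(sprintf("epoch %3d  train %.5f  val %.5f", epoch,
                      mean(batch_losses), val_loss))
    if (val_loss < best_val) {  # strict: earliest epoch wins ties
      best_val <- val_loss; best_theta <- theta; best_epoch <- epoch
      stale <- 0L
    } else {
      stale <- stale + 1L
      if (stale >= tc$early_stop_patience) break
    }
  }

  model$params <- best_theta
  model$mask <- train_set[[1L]]$mask
  model$b_mode <- tc$b_mode
  history <- data.frame(epoch = seq_along(train_hist),
                        train_loss = train_hist, val_loss = val_hist)
  attr(history, "best_epoch") <- best_epoch
  list(model = model, history = history)
}

#' Four-seed robustness protocol
#'
#' Retrains the same architecture once per seed in `tc$seeds` and reports
#' the average Pearson correlation on an evaluation set for each run,
#' together with the observed range — the check that the fit quality does
#' not hinge on a particular initialization.
#'
#' @inheritParams train_model
#' @param eval_set Encodings to score each trained model on.
#' @return `data.frame` with one row per seed (`seed`, `avg_pcc`), with a
#'   `range` attribute `c(min, max)`.
#' @export
seed_robustness <- function(config, tc, train_set, val_set, eval_set) {
  rows <- lapply(tc$seeds, function(s) {
    fit <- train_model(config, tc, train_set, val_set, seed = s)
    rep <- evaluate_dataset(fit$model, eval_set)
    data.frame(seed = s, avg_pcc = rep$average_pcc)
  })
  out <- do.call(rbind, rows)
  attr(out, "range") <- range(out$avg_pcc)
  out
}

#' Save a predictor checkpoint as plain text
#'
#' Writes `config.json` (architecture, seed, mask, target mode) and
#' `weights.txt` (one value per line, full precision) into `dir`.
#'
#' @param model A `bf_predictor`.
#' @param dir Checkpoint directory (created if needed).
#' @return `dir`, invisibly.
#' @export
save_checkpoint <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- list(config = unclass(model$config), seed = model$seed,
               mask = if (!is.null(model$mask)) unclass(model$mask),
               b_mode = model$b_mode,
               n_params = length(model$params))
  jsonlite::write_json(meta, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  writeLines(sprintf("%.17g", model$params), file.path(dir, "weights.txt"))
  invisible(dir)
}

#' Load a predictor checkpoint
#'
#' Fails loudly when the stored weight count does not match the stored
#' configuration.
#'
#' @param dir Checkpoint directory written by [save_checkpoint()].
#' @return A `bf_predictor`.
#' @export
load_checkpoint <- function(dir) {
  meta <- jsonlite::fromJSON(file.path(dir, "config.json"))
  config <- do.call(model_config, meta$config)
  params <- as.numeric(readLines(file.path(dir, "weights.txt")))
  expected <- count_parameters(config)
  if (length(params) != expected || length(params) != meta$n_params)
    stop("checkpoint mismatch: ", length(params), " weights for a config of ",
         expected)
  mask <- if (!is.null(meta$mask)) do.call(feature_mask, as.list(meta$mask))
  structure(list(config = config, params = params,
                 seed = as.integer(meta$seed), mask = mask,
                 b_mode = meta$b_mode),
            class = "bf_predictor")
}
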