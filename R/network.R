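#' Stochastic multi-residual encoder-decoder configuration
#'
#' Configuration of the segmentation network: a MultiRes-block U-shaped
#' encoder-decoder with residual-path skip connections and a permanently
#' active spatial dropout layer at the end of every MultiRes block. Each
#' MultiRes block chains three 3x3 convolutions whose concatenated outputs
#' (with `W = alpha * U` filters split roughly 1/6, 1/3, 1/2) are summed with
#' a batch-normalised 1x1 shortcut; each Res path is `L` repeated
#' conv+shortcut units of `F` filters. Because dropout never switches off,
#' every forward pass is a Monte Carlo sample.
#'
#' @param base_filters_U Integer vector, one per encoder level, strictly
#'   increasing with depth. The bottleneck uses `2 * max(U)`.
#' @param respath_filters_F Filters per Res-path unit, one per level.
#' @param respath_length_L Units per Res path, one per level, non-increasing
#'   toward deeper skips.
#' @param dropout_rate_r Spatial dropout rate in `[0, 1)`, default 0.3.
#' @param levels Number of encoder levels (resolution halvings), default 4.
#' @param alpha MultiRes width scale factor, default 1.67.
#' @param input_channels Number of input channels (1 for grayscale CMR).
#' @return An object of class `network_config`.
#' @export
network_config <- function(base_filters_U = c(32, 64, 128, 256),
                           respath_filters_F = base_filters_U,
                           respath_length_L = rev(seq_along(base_filters_U)),
                           dropout_rate_r = 0.3,
                           levels = length(base_filters_U),
                           alpha = 1.67,
                           input_channels = 1L) {
  assert_that(levels == length(base_filters_U),
              "base_filters_U must have one entry per level")
  assert_that(all(diff(base_filters_U) > 0),
              "base_filters_U must increase with depth")
  assert_that(length(respath_filters_F) == levels &&
                length(respath_length_L) == levels,
              "respath parameters must have one entry per level")
  assert_that(all(diff(respath_length_L) <= 0),
              "respath_length_L must be non-increasing with depth")
  assert_that(dropout_rate_r >= 0 && dropout_rate_r < 1,
              "dropout_rate_r must lie in [0, 1)")
  structure(list(base_filters_U = as.integer(base_filters_U),
                 respath_filters_F = as.integer(respath_filters_F),
                 respath_length_L = as.integer(respath_length_L),
                 dropout_rate_r = dropout_rate_r,
                 levels = as.integer(levels), alpha = alpha,
                 input_channels = as.integer(input_channels)),
            class = "network_config")
}

# 1/6, 1/3, 1/2 split of W = alpha * U across the three chained convolutions.
multires_filters <- function(U, alpha) {
  W <- alpha * U
  f <- pmax(1L, as.integer(round(c(W / 6, W / 3, W / 2))))
  list(f = f, total = sum(f))
}

#' Build the stochastic network
#'
#' Initialises all parameters (He-normal weights, unit batch-norm gain) from
#' the session RNG, so `set.seed()` before building gives a reproducible
#' model. The network is fully convolutional: any input whose side lengths
#' are divisible by `2^levels` is accepted at forward time.
#'
#' @param cfg A [network_config()].
#' @return An object of class `patmc_model`.
#' @export
build_network <- function(cfg = network_config()) {
  model <- new.env(parent = emptyenv())
  model$cfg <- cfg
  model$params <- new.env(parent = emptyenv())
  model$bn_state <- new.env(parent = emptyenv())
  run_net(model, x = NULL, tape = NULL, training = FALSE)  # init pass
  class(model) <- "patmc_model"
  model
}

#' @export
print.patmc_model <- function(x, ...) {
  cat(sprintf(
    "<patmc_model> %d levels, U = (%s), r = %.2f, %s parameters\n",
    x$cfg$levels, paste(x$cfg$base_filters_U, collapse = ", "),
    x$cfg$dropout_rate_r, format(n_parameters(x), big.mark = ",")))
  invisible(x)
}

#' Total trainable parameter count
#' @param model A `patmc_model`.
#' @return Integer.
#' @export
n_parameters <- function(model) {
  sum(vapply(ls(model$params), function(nm) length(model$params[[nm]]),
             numeric(1)))
}

# The architecture, written once. With x = NULL the function only walks the
# graph creating parameters (channel bookkeeping via lightweight `list(ch=)`
# stand-ins); with a real (H, W, C, B) array it runs the forward pass on the
# given tape. `dropout` = FALSE is an evaluation-mode override for tests.
run_net <- function(model, x, tape, training, dropout = TRUE) {
  init <- is.null(x)
  cfg <- model$cfg
  P <- model$params
  pnodes <- new.env(parent = emptyenv())
  if (!is.null(tape)) tape$pnodes <- pnodes  # for gradient retrieval

  getp <- function(name) {
    if (is.null(pnodes[[name]])) {
      pnodes[[name]] <- ag_node(tape, P[[name]], name = name)
    }
    pnodes[[name]]
  }
  he_init <- function(kh, kw, cin, f) {
    array(stats::rnorm(kh * kw * cin * f, sd = sqrt(2 / (kh * kw * cin))),
          c(kh, kw, cin, f))
  }

  CONV <- function(name, k, xin, f) {
    if (init) {
      if (is.null(P[[paste0(name, ".w")]])) {
        P[[paste0(name, ".w")]] <- he_init(k, k, xin$ch, f)
        P[[paste0(name, ".b")]] <- numeric(f)
      }
      return(list(ch = f))
    }
    ag_conv(tape, xin, getp(paste0(name, ".w")), getp(paste0(name, ".b")))
  }
  CONVT <- function(name, xin, f) {
    if (init) {
      if (is.null(P[[paste0(name, ".w")]])) {
        P[[paste0(name, ".w")]] <- he_init(2, 2, xin$ch, f)
        P[[paste0(name, ".b")]] <- numeric(f)
      }
      return(list(ch = f))
    }
    ag_convt2(tape, xin, getp(paste0(name, ".w")), getp(paste0(name, ".b")))
  }
  BN <- function(name, xin) {
    if (init) {
      if (is.null(P[[paste0(name, ".g")]])) {
        P[[paste0(name, ".g")]] <- rep(1, xin$ch)
        P[[paste0(name, ".be")]] <- numeric(xin$ch)
      }
      return(xin)
    }
    ag_bn(tape, xin, getp(paste0(name, ".g")), getp(paste0(name, ".be")),
          model$bn_state, name, training)
  }
  RELU <- function(xin) if (init) xin else ag_relu(tape, xin)
  ADD <- function(a, b) if (init) a else ag_add(tape, a, b)
  POOL <- function(xin) if (init) xin else ag_pool(tape, xin)
  CAT <- function(xs) {
    if (init) list(ch = sum(vapply(xs, function(x) x$ch, numeric(1))))
    else ag_concat(tape, xs)
  }
  DROP <- function(xin) {
    if (init || !dropout) xin
    else ag_dropout_spatial(tape, xin, cfg$dropout_rate_r)
  }

  multires_block <- function(name, xin, U) {
    mf <- multires_filters(U, cfg$alpha)
    sc <- BN(paste0(name, ".sc_bn"), CONV(paste0(name, ".sc"), 1, xin, mf$total))
    c1 <- RELU(BN(paste0(name, ".bn1"), CONV(paste0(name, ".c1"), 3, xin, mf$f[1])))
    c2 <- RELU(BN(paste0(name, ".bn2"), CONV(paste0(name, ".c2"), 3, c1, mf$f[2])))
    c3 <- RELU(BN(paste0(name, ".bn3"), CONV(paste0(name, ".c3"), 3, c2, mf$f[3])))
    cc <- BN(paste0(name, ".cat_bn"), CAT(list(c1, c2, c3)))
    DROP(BN(paste0(name, ".out_bn"), RELU(ADD(cc, sc))))
  }
  respath <- function(name, xin, f, len) {
    for (u in seq_len(len)) {
      nm <- sprintf("%s.u%d", name, u)
      main <- BN(paste0(nm, ".bn3"), CONV(paste0(nm, ".c3"), 3, xin, f))
      sc <- BN(paste0(nm, ".bn1"), CONV(paste0(nm, ".c1"), 1, xin, f))
      xin <- BN(paste0(nm, ".out_bn"), RELU(ADD(main, sc)))
    }
    xin
  }

  if (!init) {
    d <- dim(x)
    assert_that(all(d[1:2] %% 2^cfg$levels == 0),
                sprintf("input shape must be divisible by %d", 2^cfg$levels))
    x <- ag_node(tape, x)
  } else {
    x <- list(ch = cfg$input_channels)
  }

  skips <- vector("list", cfg$levels)
  for (l in seq_len(cfg$levels)) {
    e <- multires_block(sprintf("enc%d", l), x, cfg$base_filters_U[l])
    skips[[l]] <- respath(sprintf("skip%d", l), e, cfg$respath_filters_F[l],
                          cfg$respath_length_L[l])
    x <- POOL(e)
  }
  x <- multires_block("bottleneck", x, 2L * cfg$base_filters_U[cfg$levels])
  for (l in rev(seq_len(cfg$levels))) {
    up <- CONVT(sprintf("dec%d.up", l), x, cfg$respath_filters_F[l])
    x <- multires_block(sprintf("dec%d", l), CAT(list(up, skips[[l]])),
                        cfg$base_filters_U[l])
  }
  CONV("final", 1, x, 1L)
}

#' One stochastic forward pass
#'
#' Runs the network once with dropout active (its permanent state), producing
#' a probability map that differs between calls unless the dropout rate is
#' zero or the RNG is reseeded. Batch-norm uses its running estimates, so all
#' stochasticity comes from the dropout draw.
#'
#' @param model A `patmc_model`.
#' @param img A preprocessed [grayscale_image()] (matrix allowed) whose side
#'   lengths are divisible by `2^levels`.
#' @param rng_seed Optional seed; a fixed seed reproduces the draw exactly.
#' @param dropout Set `FALSE` to disable dropout (deterministic evaluation
#'   override intended for testing only; the method itself never switches
#'   dropout off).
#' @return A [probability_map()].
#' @export
forward_sample <- function(model, img, rng_seed = NULL, dropout = TRUE) {
  img <- as_image(img)
  if (!is.null(rng_seed)) set.seed(rng_seed)
  d <- dim(img$pixels)
  x <- array(img$pixels, c(d, 1L, 1L))
  logits <- run_net(model, x, tape = NULL, training = FALSE, dropout = dropout)
  probability_map(matrix(sigmoid(logits$value), d[1], d[2]), img$spacing_mm)
}

# Deep snapshot/restore of parameters and batch-norm running state, used by
# best-weights restoration and checkpointing.
snapshot_model <- function(model) {
  list(params = as.list(model$params), bn = as.list(model$bn_state))
}

restore_model <- function(model, snap) {
  for (nm in names(snap$params)) model$params[[nm]] <- snap$params[[nm]]
  rm(list = setdiff(ls(model$bn_state), names(snap$bn)), envir = model$bn_state)
  for (nm in names(snap$bn)) model$bn_state[[nm]] <- snap$bn[[nm]]
  invisible(model)
}

#' Save / load a model checkpoint
#'
#' The checkpoint is a self-describing list (config snapshot, parameters,
#' batch-norm running statistics, package version) serialised with
#' [saveRDS()].
#'
#' @param model A `patmc_model`.
#' @param path Destination file.
#' @return `path` (save) or a `patmc_model` (load).
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(list(cfg = model$cfg, snapshot = snapshot_model(model),
               version = as.character(utils::packageVersion("patmc"))),
          path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  model <- build_network(ck$cfg)
  restore_model(model, ck$snapshot)
  model
}
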