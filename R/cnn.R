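## Public CNN API: configuration, construction, weighted cross-entropy,
## training with the validation stopping rule, seed-controlled retraining,
## and patch prediction.

labelIndex <- function(labels) {
  if (is.numeric(labels)) {
    stopifnot(all(labels %in% 1:3))
    return(as.integer(labels))
  }
  i <- match(labels, srhClasses())
  if (anyNA(i)) stop("invalid class label(s)", call. = FALSE)
  i
}

#' Residual network configuration
#'
#' Describes a pre-activation residual classifier. The desk profile (the
#' default) is a compact two-stage basic-block network on 25 x 25 px
#' mean-pooled patches, sized for CPU training; `block_type = "bottleneck"`
#' with stage widths `c(256, 512, 1024, 2048)` and `blocks_per_stage
#' c(3, 4, 6, 3)` reproduces the ResNet50v2 stage topology for full-scale
#' 300 x 300 px work (with the stem pooling folded into a strided stem
#' convolution). Optimizer settings are defaults, not reported values.
#'
#' @param stage_widths integer vector of channel counts per residual stage.
#' @param blocks_per_stage blocks per stage (scalar or per-stage vector).
#' @param block_type `"basic"` (two 3x3 convolutions) or `"bottleneck"`
#'   (1x1 / 3x3 / 1x1).
#' @param input_px input patch side length after pooling.
#' @param n_classes number of output classes (3).
#' @param stem_kernel,stem_stride stem convolution geometry.
#' @param seed integer seed controlling parameter initialization and
#'   training-time shuffling.
#' @param lr,batch_size,rho RMSProp learning rate, minibatch size and decay.
#' @param bn_momentum running-moment momentum for batch normalization.
#' @return A validated `ModelConfig` list.
#' @export
#' @examples
#' cfg <- modelConfig(stage_widths = c(8, 16), seed = 1)
modelConfig <- function(stage_widths = c(8, 16), blocks_per_stage = 1L,
                        block_type = c("basic", "bottleneck"),
                        input_px = 25L, n_classes = 3L,
                        stem_kernel = 3L, stem_stride = 1L, seed = 1L,
                        lr = 1e-3, batch_size = 64L, rho = 0.9,
                        bn_momentum = 0.9) {
  block_type <- match.arg(block_type)
  if (length(stage_widths) < 1L || any(stage_widths < 1))
    stop("need at least one residual stage with positive width",
         call. = FALSE)
  if (n_classes < 2L) stop("need at least 2 classes", call. = FALSE)
  if (block_type == "bottleneck" && any(stage_widths %% 4 != 0))
    stop("bottleneck stage widths must be multiples of 4", call. = FALSE)
  cfg <- list(stage_widths = as.integer(stage_widths),
              blocks_per_stage = as.integer(blocks_per_stage),
              block_type = block_type,
              input_px = as.integer(input_px),
              n_classes = as.integer(n_classes),
              stem_kernel = as.integer(stem_kernel),
              stem_stride = as.integer(stem_stride),
              seed = as.integer(seed),
              lr = lr, batch_size = as.integer(batch_size), rho = rho,
              bn_momentum = bn_momentum)
  ## spatial size surviving the downsampling path
  s <- (input_px - 1L) %/% cfg$stem_stride + 1L
  for (i in seq_along(stage_widths)[-1]) s <- (s - 1L) %/% 2L + 1L
  if (s < 2L)
    stop("input size ", input_px,
         " px is incompatible with the downsampling depth (",
         length(stage_widths), " stages leave ", s, " px)", call. = FALSE)
  class(cfg) <- c("ModelConfig", "list")
  cfg
}

heInit <- function(dims, fan_in) {
  array(stats::rnorm(prod(dims), 0, sqrt(2 / fan_in)), dims)
}

#' Build a residual CNN classifier
#'
#' Constructs the pre-activation residual network described by the
#' configuration: stem convolution, residual stages with identity shortcuts
#' (1x1 projections where shape changes), batch normalization, global
#' average pooling and a 3-way softmax head. Parameter initialization
#' (He normal) is fully determined by `config$seed`.
#'
#' @param config a `ModelConfig` from [modelConfig()].
#' @return An untrained [SRHModel-class].
#' @export
buildModel <- function(config) {
  stopifnot(inherits(config, "ModelConfig"))
  k <- config$stem_kernel
  params <- withSeed(config$seed, {
    p <- list(stem = heInit(c(k, k, 3L, config$stage_widths[1]), k * k * 3))
    for (bl in cnnBlockPlan(config)) {
      pre <- bl$prefix
      if (config$block_type == "basic") {
        p[[paste0(pre, "bn1_gamma")]] <- rep(1, bl$cin)
        p[[paste0(pre, "bn1_beta")]] <- rep(0, bl$cin)
        p[[paste0(pre, "conv1")]] <-
          heInit(c(3L, 3L, bl$cin, bl$cout), 9 * bl$cin)
        p[[paste0(pre, "bn2_gamma")]] <- rep(1, bl$cout)
        p[[paste0(pre, "bn2_beta")]] <- rep(0, bl$cout)
        p[[paste0(pre, "conv2")]] <-
          heInit(c(3L, 3L, bl$cout, bl$cout), 9 * bl$cout)
      } else {
        mid <- bl$cout %/% 4L
        p[[paste0(pre, "bn1_gamma")]] <- rep(1, bl$cin)
        p[[paste0(pre, "bn1_beta")]] <- rep(0, bl$cin)
        p[[paste0(pre, "conv1")]] <- heInit(c(1L, 1L, bl$cin, mid), bl$cin)
        p[[paste0(pre, "bn2_gamma")]] <- rep(1, mid)
        p[[paste0(pre, "bn2_beta")]] <- rep(0, mid)
        p[[paste0(pre, "conv2")]] <- heInit(c(3L, 3L, mid, mid), 9 * mid)
        p[[paste0(pre, "bn3_gamma")]] <- rep(1, mid)
        p[[paste0(pre, "bn3_beta")]] <- rep(0, mid)
        p[[paste0(pre, "conv3")]] <- heInit(c(1L, 1L, mid, bl$cout), mid)
      }
      if (bl$proj)
        p[[paste0(pre, "proj")]] <-
          heInit(c(1L, 1L, bl$cin, bl$cout), bl$cin)
    }
    wS <- utils::tail(config$stage_widths, 1L)
    p$head_bn_gamma <- rep(1, wS)
    p$head_bn_beta <- rep(0, wS)
    p$dense_W <- matrix(stats::rnorm(config$n_classes * wS, 0,
                                     sqrt(2 / wS)),
                        config$n_classes, wS)
    p$dense_b <- rep(0, config$n_classes)
    p
  })
  bnrun <- list()
  for (bl in cnnBlockPlan(config)) {
    bnrun[[paste0(bl$prefix, "bn1")]] <-
      list(mu = rep(0, bl$cin), var = rep(1, bl$cin))
    if (config$block_type == "basic") {
      bnrun[[paste0(bl$prefix, "bn2")]] <-
        list(mu = rep(0, bl$cout), var = rep(1, bl$cout))
    } else {
      mid <- bl$cout %/% 4L
      bnrun[[paste0(bl$prefix, "bn2")]] <- list(mu = rep(0, mid),
                                                var = rep(1, mid))
      bnrun[[paste0(bl$prefix, "bn3")]] <- list(mu = rep(0, mid),
                                                var = rep(1, mid))
    }
  }
  wS <- utils::tail(config$stage_widths, 1L)
  bnrun$head_bn <- list(mu = rep(0, wS), var = rep(1, wS))
  new("SRHModel", config = unclass(config), params = params,
      state = list(bnrun = bnrun, opt = list()),
      trainState = list(history = NULL, stopped = FALSE))
}

#' Class-weighted categorical cross-entropy
#'
#' `loss = -w_label * log(p_label)`, averaged over a batch; probabilities are
#' clamped at 1e-12 so the loss is never infinite. With unit weights this is
#' the ordinary categorical cross-entropy.
#'
#' @param prob numeric(3) probability vector or 3 x n matrix (columns on the
#'   simplex).
#' @param label class label(s) (names or indices), length n.
#' @param weights named numeric(3) class weights, e.g. from [classWeights()].
#' @return Mean loss (scalar).
#' @export
#' @examples
#' weightedCrossEntropy(c(0.5, 0.25, 0.25), "tumor",
#'                      c(tumor = 2, non_tumor = 0.5, low_quality = 0.5))
weightedCrossEntropy <- function(prob, label,
                                 weights = c(tumor = 1, non_tumor = 1,
                                             low_quality = 1)) {
  if (is.null(dim(prob))) prob <- matrix(prob, ncol = 1L)
  y <- labelIndex(label)
  stopifnot(ncol(prob) == length(y), nrow(prob) == 3L, all(weights > 0))
  w <- if (!is.null(names(weights))) as.numeric(weights[srhClasses()])
       else as.numeric(weights)
  if (length(w) != 3L || anyNA(w))
    stop("weights must cover the three classes", call. = FALSE)
  p <- pmax(prob[cbind(y, seq_along(y))], 1e-12)
  mean(-w[y] * log(p))
}

#' The validation stopping rule
#'
#' Training stops at the first epoch whose preliminary validation accuracy
#' exceeds the accuracy threshold AND whose validation loss falls below the
#' loss threshold (a conjunction; satisfying only one continues training).
#'
#' @param val_accuracy,val_loss epoch-end validation metrics.
#' @param acc_threshold accuracy that must be exceeded (default 0.95).
#' @param loss_threshold loss that must be undercut (default 0.10).
#' @return Logical.
#' @export
#' @examples
#' stopCriterion(0.96, 0.05)  # TRUE
#' stopCriterion(0.96, 0.20)  # FALSE: loss still too high
stopCriterion <- function(val_accuracy, val_loss, acc_threshold = 0.95,
                          loss_threshold = 0.10) {
  isTRUE(val_accuracy > acc_threshold) && isTRUE(val_loss < loss_threshold)
}

evalModel <- function(model, x, y, weights, chunk = 256L) {
  n <- dim(x)[4]
  probs <- matrix(0, 3L, n)
  i <- 1L
  while (i <= n) {
    j <- min(i + chunk - 1L, n)
    fw <- cnnForward(model@params, model@config, model@state$bnrun,
                     x[, , , i:j, drop = FALSE], train = FALSE)
    probs[, i:j] <- softmaxProbs(fw$logits)
    i <- j + 1L
  }
  top1 <- max.col(t(probs), ties.method = "first")
  list(probs = probs,
       accuracy = mean(top1 == y),
       loss = weightedCrossEntropy(probs, y, weights))
}

#' Train the residual CNN
#'
#' Minibatch RMSProp on class-weighted categorical cross-entropy. After
#' every epoch the model is evaluated on the validation split; training
#' stops at the first epoch satisfying [stopCriterion()] (accuracy above
#' `stop_acc` and weighted validation loss below `stop_loss`), or at
#' `max_epochs` with `stopped = FALSE` flagged in the training state. All
#' randomness (shuffling) derives from `seed`. If the training loss turns
#' non-finite the run aborts at the last finite state with
#' `diverged = TRUE`.
#'
#' @param model an [SRHModel-class] from [buildModel()].
#' @param train,val lists with `x` (input_px x input_px x 3 x n array) and
#'   `y` (labels); both non-empty, the training split with at least 2
#'   classes.
#' @param weights named class weights from [classWeights()].
#' @param stop_acc,stop_loss stopping thresholds.
#' @param max_epochs safety cap (the criterion may never trigger on hard
#'   data).
#' @param seed shuffle seed; defaults to the model's configuration seed.
#' @return The trained [SRHModel-class]; `trainHistory()` gives the
#'   per-epoch record.
#' @export
trainCNN <- function(model, train, val,
                     weights = c(tumor = 1, non_tumor = 1, low_quality = 1),
                     stop_acc = 0.95, stop_loss = 0.10, max_epochs = 100L,
                     seed = NULL) {
  stopifnot(is(model, "SRHModel"))
  ytr <- labelIndex(train$y); yva <- labelIndex(val$y)
  if (length(ytr) == 0L || length(yva) == 0L)
    stop("training and validation splits must be non-empty", call. = FALSE)
  if (length(unique(ytr)) < 2L)
    stop("training split must contain at least 2 classes", call. = FALSE)
  w <- as.numeric(weights[srhClasses()])
  if (anyNA(w)) w <- as.numeric(weights)
  seed <- seed %||% model@config$seed
  cfg <- model@config
  params <- model@params
  opt <- model@state$opt
  bnrun <- model@state$bnrun
  n <- length(ytr)
  bs <- min(cfg$batch_size, n)
  history <- NULL
  stopped <- FALSE; diverged <- FALSE
  withSeed(seed + 1L, {
    for (epoch in seq_len(max_epochs)) {
      perm <- sample(n)
      ep_loss <- 0; nb <- 0L
      for (start in seq(1L, n, by = bs)) {
        bi <- perm[start:min(start + bs - 1L, n)]
        xb <- train$x[, , , bi, drop = FALSE]
        yb <- ytr[bi]
        fw <- cnnForward(params, cfg, bnrun, xb, train = TRUE)
        bnrun <- fw$bnrun
        p <- softmaxProbs(fw$logits)
        wl <- w[yb]
        loss <- mean(-wl * log(pmax(p[cbind(yb, seq_along(yb))], 1e-12)))
        if (!is.finite(loss)) { diverged <- TRUE; break }
        G <- p
        G[cbind(yb, seq_along(yb))] <- G[cbind(yb, seq_along(yb))] - 1
        dlogits <- G * rep(wl, each = 3L) / length(yb)
        grads <- cnnBackward(dlogits, fw$caches, cfg)
        up <- rmspropStep(params, grads, opt, cfg$lr, cfg$rho)
        params <- up$params; opt <- up$opt
        ep_loss <- ep_loss + loss; nb <- nb + 1L
      }
      if (diverged) break
      tmp_model <- model
      tmp_model@params <- params
      tmp_model@state <- list(bnrun = bnrun, opt = opt)
      ev <- evalModel(tmp_model, val$x, yva, w)
      history <- rbind(history,
                       data.frame(epoch = epoch,
                                  train_loss = ep_loss / nb,
                                  val_accuracy = ev$accuracy,
                                  val_loss = ev$loss))
      if (stopCriterion(ev$accuracy, ev$loss, stop_acc, stop_loss)) {
        stopped <- TRUE
        break
      }
    }
  })
  model@params <- params
  model@state <- list(bnrun = bnrun, opt = opt)
  last <- if (is.null(history)) data.frame(val_accuracy = NA_real_,
                                           val_loss = NA_real_)
          else history[nrow(history), ]
  model@trainState <- list(history = history, stopped = stopped,
                           diverged = diverged,
                           val_accuracy = last$val_accuracy,
                           val_loss = last$val_loss,
                           seed = seed,
                           stop_acc = stop_acc, stop_loss = stop_loss)
  model
}

#' Retrain the classifier with different random seeds
#'
#' Trains one model per seed on the same data (the study's
#' reliability-analysis design: the network retrained a second and a third
#' time with different random seeds). Seeds must be pairwise distinct. A
#' member that fails its stopping criterion flags the ensemble but does not
#' abort it.
#'
#' @param config a `ModelConfig`; its seed field is replaced per member.
#' @param data list with `train`, `val` (as in [trainCNN()]) and optional
#'   `weights`.
#' @param seeds integer vector of distinct seeds (default length 3).
#' @param ... forwarded to [trainCNN()].
#' @return List with `models` (list of [SRHModel-class]) and `flagged`
#'   (TRUE if any member did not reach the stopping criterion).
#' @export
retrainEnsemble <- function(config, data, seeds = c(1L, 2L, 3L), ...) {
  if (anyDuplicated(seeds))
    stop("ensemble seeds must be pairwise distinct", call. = FALSE)
  weights <- data$weights %||% c(tumor = 1, non_tumor = 1, low_quality = 1)
  models <- lapply(seeds, function(s) {
    cfg <- config
    cfg$seed <- as.integer(s)
    trainCNN(buildModel(cfg), data$train, data$val, weights = weights,
             seed = s, ...)
  })
  list(models = models,
       flagged = !all(vapply(models, function(m) m@trainState$stopped,
                             logical(1))))
}

#' Predict class probabilities for patches
#'
#' Evaluation-mode forward pass (batch-norm running moments, so batched and
#' single evaluation agree). Patches larger than the configured input size
#' are mean-pooled down automatically (e.g. 300 px windows to the desk
#' profile's 25 px input).
#'
#' @param model a trained [SRHModel-class].
#' @param x array `s x s x 3 x n` (or `s x s x 3` for a single patch).
#' @return Matrix n x 3 of class probabilities (columns in canonical order).
#' @export
predictPatches <- function(model, x) {
  stopifnot(is(model, "SRHModel"))
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  if (length(dim(x)) != 4L || dim(x)[3] != 3L)
    stop("patches must be an s x s x 3 x n array", call. = FALSE)
  s <- model@config$input_px
  if (dim(x)[1] != s) {
    pooled <- array(0, c(s, s, 3L, dim(x)[4]))
    for (i in seq_len(dim(x)[4]))
      pooled[, , , i] <- poolPatch(x[, , , i, drop = TRUE], s)
    x <- pooled
  }
  n <- dim(x)[4]
  probs <- matrix(0, 3L, n)
  i <- 1L
  while (i <= n) {
    j <- min(i + 255L, n)
    fw <- cnnForward(model@params, model@config, model@state$bnrun,
                     x[, , , i:j, drop = FALSE], train = FALSE)
    probs[, i:j] <- softmaxProbs(fw$logits)
    i <- j + 1L
  }
  out <- t(probs)
  colnames(out) <- srhClasses()
  out
}

#' @rdname predictPatches
#' @param patch a single `s x s x 3` patch.
#' @return `predictPatch`: list with `p` (named probability 3-vector) and
#'   `top1` (argmax class under the canonical tie rule).
#' @export
predictPatch <- function(model, patch) {
  if (length(dim(patch)) != 3L || dim(patch)[3] != 3L)
    stop("patch must be an s x s x 3 array", call. = FALSE)
  p <- predictPatches(model, patch)[1L, ]
  list(p = p, top1 = srhClasses()[which.max(p)])
}
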