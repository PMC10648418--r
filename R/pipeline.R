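# Subject-wise experimental scaffolding: 7:2:1 splits that never place two
# images of one subject in different partitions, training loops for SAMD
# and gradient-descent baselines, and ACC/SEN/SPE/AUC evaluation.

.TASKS <- list(
  AD_vs_NC = list(negative = "NC", positive = "AD"),
  sMCI_vs_pMCI = list(negative = "sMCI", positive = "pMCI")
)

#' Split specification
#'
#' @param ratios Train/validation/test fractions summing to 1.
#' @param seed Integer seed for the subject shuffle.
#' @return An object of class `split_spec`; the split unit is always the
#'   subject.
#' @export
split_spec <- function(ratios = c(0.7, 0.2, 0.1), seed = 1L) {
  stopifnot(length(ratios) == 3, all(ratios >= 0),
            abs(sum(ratios) - 1) < 1e-9)
  structure(list(ratios = ratios, seed = as.integer(seed), unit = "subject"),
            class = "split_spec")
}

# largest-remainder apportionment of n subjects into three sets; ties and
# empty sets resolved toward populating validation/test
.apportion <- function(n, ratios) {
  target <- n * ratios
  k <- floor(target)
  rem <- target - k
  leftover <- n - sum(k)
  while (leftover > 0) {
    ord <- order(-rem, k)  # largest remainder, then emptier set
    i <- ord[1]
    k[i] <- k[i] + 1
    rem[i] <- 0
    leftover <- leftover - 1
  }
  while (any(k == 0)) {
    k[which.max(k)] <- max(k) - 1
    k[which(k == 0)[1]] <- 1
  }
  k
}

.subset_cohort <- function(cohort, keep) {
  structure(list(samples = cohort$samples[keep],
                 manifest = cohort$manifest[keep, ],
                 counts = table(cohort$manifest$label[keep])),
            class = "cohort")
}

#' Subject-wise train/validation/test split
#'
#' Shuffles subjects within each class with the seeded stream and
#' partitions them as close to the requested ratios as integer counts
#' allow (largest-remainder rounding; every partition receives at least
#' one subject per class). All images follow their subject, so the three
#' subject sets are pairwise disjoint.
#'
#' @param cohort A [generate_cohort()] cohort.
#' @param spec A [split_spec()].
#' @return A list with cohorts `train`, `val` and `test`.
#' @export
subject_split <- function(cohort, spec = split_spec()) {
  stopifnot(inherits(cohort, "cohort"), inherits(spec, "split_spec"))
  mf <- cohort$manifest
  set.seed(spec$seed)
  assign_set <- character(nrow(mf))
  for (cls in sort(unique(mf$label))) {
    subs <- unique(mf$subject_id[mf$label == cls])
    if (length(subs) < 3) {
      stop("class ", cls, " has fewer than 3 subjects; cannot populate ",
           "train, validation and test", call. = FALSE)
    }
    subs <- sample(subs)
    k <- .apportion(length(subs), spec$ratios)
    sets <- rep(c("train", "val", "test"), times = k)
    for (i in seq_along(subs)) {
      assign_set[mf$subject_id == subs[i]] <- sets[i]
    }
  }
  list(train = .subset_cohort(cohort, assign_set == "train"),
       val = .subset_cohort(cohort, assign_set == "val"),
       test = .subset_cohort(cohort, assign_set == "test"))
}

#' Training configuration
#'
#' @param task `"AD_vs_NC"` (positive class AD) or `"sMCI_vs_pMCI"`
#'   (positive class pMCI).
#' @param optimizer `"samd"`, `"sgd"`, `"adam"`, or `"wobmd"` (SAMD with
#'   the correction factor forced to 1).
#' @param epochs,batch_size Training loop sizes.
#' @param base_lr Base learning rate.
#' @param samd A [samd_config()] for the SAMD update.
#' @param seed Integer seed controlling initialization-independent
#'   randomness (batch order).
#' @return An object of class `train_config`.
#' @export
train_config <- function(task = c("AD_vs_NC", "sMCI_vs_pMCI"),
                         optimizer = c("samd", "sgd", "adam", "wobmd"),
                         epochs = 10L, batch_size = 4L, base_lr = 0.01,
                         samd = samd_config(), seed = 1L) {
  task <- match.arg(task)
  optimizer <- match.arg(optimizer)
  stopifnot(epochs >= 0, batch_size >= 1, base_lr > 0)
  structure(list(task = task, optimizer = optimizer,
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), base_lr = base_lr,
                 samd = samd, seed = as.integer(seed)),
            class = "train_config")
}

# stack the task's samples into a (side,side,side,1,N) tensor plus labels
# (1 = negative, 2 = positive)
.cohort_tensors <- function(cohort, task) {
  tk <- .TASKS[[task]]
  if (is.null(tk)) stop("unknown task: ", task, call. = FALSE)
  keep <- cohort$manifest$label %in% c(tk$negative, tk$positive)
  if (!any(keep)) stop("task labels absent from cohort", call. = FALSE)
  samples <- cohort$samples[keep]
  labels <- ifelse(cohort$manifest$label[keep] == tk$positive, 2L, 1L)
  side <- dim(samples[[1]]$voxels)[1]
  x <- array(0, c(side, side, side, 1, length(samples)))
  for (i in seq_along(samples)) x[, , , 1, i] <- samples[[i]]$voxels
  list(x = x, y = labels,
       subject = cohort$manifest$subject_id[keep])
}

.predict_scores <- function(model, x, batch = 8L) {
  n <- dim(x)[5]
  scores <- numeric(n)
  preds <- integer(n)
  i <- 1L
  while (i <= n) {
    j <- min(i + batch - 1L, n)
    logits <- arcnn_predict(model, x[, , , , i:j, drop = FALSE])
    z <- logits - apply(logits, 1, max)
    p <- exp(z) / rowSums(exp(z))
    scores[i:j] <- p[, 2]
    preds[i:j] <- max.col(logits, ties.method = "first")
    i <- j + 1L
  }
  list(scores = scores, preds = preds)
}

.accuracy <- function(model, x, y) {
  mean(.predict_scores(model, x)$preds == y)
}

# evaluation-time parameter vector: the SAMD running average, else the raw
# parameters
.eval_params <- function(p, opt_state, optimizer) {
  if (optimizer %in% c("samd", "wobmd")) opt_state$x_bar else p
}

#' Train an ARCNN on a binary diagnosis task
#'
#' Minimizes the cross-entropy loss on the two logits with the configured
#' optimizer. The SAMD update follows the accelerated mirror-descent
#' iteration on the flat parameter vector (Euclidean unconstrained mirror
#' step with the decaying step factor, the deviation-correction factor and
#' weighted iterate averaging); evaluation then uses the averaged
#' parameters. `"sgd"` and `"adam"` apply the classic update rules at the
#' same base learning rate. All randomness (batch order) is seeded.
#'
#' @param model A [build_arcnn()] model whose input side matches the data.
#' @param data A list with cohorts `train` and `val`.
#' @param config A [train_config()].
#' @return An object of class `arcnn_fit`: list with `model` (evaluation
#'   weights installed), `curves` (tibble of per-epoch train/validation
#'   accuracy and mean training loss) and `config`.
#' @export
train_model <- function(model, data, config) {
  stopifnot(inherits(model, "arcnn_model"), inherits(config, "train_config"))
  tr <- .cohort_tensors(data$train, config$task)
  va <- .cohort_tensors(data$val, config$task)

  p <- arcnn_flatten(model$params)
  opt <- config$optimizer
  scfg <- config$samd
  if (opt == "wobmd") scfg$beta_one <- TRUE
  opt_state <- switch(opt,
    samd = samd_state_init(p),
    wobmd = samd_state_init(p),
    adam = list(m = numeric(length(p)), v = numeric(length(p)), t = 0L),
    sgd = NULL
  )

  curves <- tibble::tibble(epoch = integer(), train_loss = numeric(),
                           train_acc = numeric(), val_acc = numeric())
  if (config$epochs == 0L) {
    return(structure(list(model = model, curves = curves, config = config),
                     class = "arcnn_fit"))
  }

  set.seed(config$seed)
  n <- length(tr$y)
  for (epoch in seq_len(config$epochs)) {
    idx <- sample(n)
    losses <- numeric(0)
    i <- 1L
    while (i <= n) {
      j <- min(i + config$batch_size - 1L, n)
      take <- idx[i:j]
      model <- .with_flat_params(model, p)
      r <- arcnn_loss_grads(model,
                            tr$x[, , , , take, drop = FALSE], tr$y[take])
      model$buffers <- r$buffers
      losses <- c(losses, r$loss)
      g <- r$grads
      if (opt %in% c("samd", "wobmd")) {
        st <- samd_network_step(p, g, opt_state, scfg,
                                base_lr = config$base_lr)
        p <- st$params
        opt_state <- st$state
      } else if (opt == "sgd") {
        p <- p - config$base_lr * g
      } else {  # adam
        opt_state$t <- opt_state$t + 1L
        opt_state$m <- 0.9 * opt_state$m + 0.1 * g
        opt_state$v <- 0.999 * opt_state$v + 0.001 * g^2
        mh <- opt_state$m / (1 - 0.9^opt_state$t)
        vh <- opt_state$v / (1 - 0.999^opt_state$t)
        p <- p - config$base_lr * mh / (sqrt(vh) + 1e-8)
      }
      i <- j + 1L
    }
    eval_model <- .with_flat_params(model, .eval_params(p, opt_state, opt))
    curves <- rbind(curves,
                    tibble::tibble(epoch = epoch,
                                   train_loss = mean(losses),
                                   train_acc = .accuracy(eval_model, tr$x,
                                                         tr$y),
                                   val_acc = .accuracy(eval_model, va$x,
                                                       va$y)))
  }
  model <- .with_flat_params(model, .eval_params(p, opt_state, opt))
  structure(list(model = model, curves = curves, config = config),
            class = "arcnn_fit")
}

#' @export
print.arcnn_fit <- function(x, ...) {
  n <- nrow(x$curves)
  cat(sprintf("<arcnn_fit> task=%s optimizer=%s epochs=%d\n",
              x$config$task, x$config$optimizer, n))
  if (n > 0) {
    cat(sprintf("  final train_acc=%.3f val_acc=%.3f\n",
                x$curves$train_acc[n], x$curves$val_acc[n]))
  }
  invisible(x)
}

#' Rank-based AUC (trapezoidal ROC area, midrank ties)
#'
#' @param scores Numeric positive-class scores.
#' @param labels Integer labels (2 = positive, 1 = negative) or logical.
#' @return The area under the ROC curve.
#' @export
rank_auc <- function(scores, labels) {
  pos <- if (is.logical(labels)) labels else labels == 2L
  np <- sum(pos); nn <- sum(!pos)
  if (np == 0 || nn == 0) return(NA_real_)
  r <- rank(scores)  # midranks on ties
  (sum(r[pos]) - np * (np + 1) / 2) / (np * nn)
}

#' Evaluate a model on a test cohort
#'
#' Hard labels come from the argmax logit; AUC from the positive-class
#' score ranking (midrank Mann-Whitney statistic, equal to the trapezoidal
#' ROC area). Sensitivity is the true-positive rate on the task's positive
#' class (AD, or pMCI), specificity the true-negative rate.
#'
#' @param model A trained `arcnn_model` (or an `arcnn_fit`).
#' @param test A test cohort containing both task classes.
#' @param task Task name as in [train_config()].
#' @return An object of class `eval_report` with fields `acc`, `sen`,
#'   `spe`, `auc`, `confusion` (2x2 integer table), `scores` (tibble of
#'   per-image scores and truths) and `degenerate` (`TRUE` when the test
#'   set has a single class and AUC is undefined).
#' @export
evaluate <- function(model, test, task) {
  if (inherits(model, "arcnn_fit")) model <- model$model
  stopifnot(inherits(model, "arcnn_model"))
  te <- .cohort_tensors(test, task)
  pr <- .predict_scores(model, te$x)
  y <- te$y
  degenerate <- length(unique(y)) < 2
  tp <- sum(pr$preds == 2 & y == 2)
  fn <- sum(pr$preds == 1 & y == 2)
  tn <- sum(pr$preds == 1 & y == 1)
  fp <- sum(pr$preds == 2 & y == 1)
  confusion <- matrix(c(tn, fp, fn, tp), 2, 2,
                      dimnames = list(predicted = c("negative", "positive"),
                                      truth = c("negative", "positive")))
  acc <- (tp + tn) / length(y)
  sen <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spe <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  auc <- rank_auc(pr$scores, y)
  if (degenerate) {
    warning("test set contains a single class; AUC undefined",
            call. = FALSE)
  }
  structure(list(acc = acc, sen = sen, spe = spe, auc = auc,
                 confusion = confusion,
                 scores = tibble::tibble(score = pr$scores,
                                         truth = y,
                                         subject = te$subject),
                 degenerate = degenerate, task = task),
            class = "eval_report")
}

#' Metrics from a 2x2 confusion table
#'
#' @param tp,fn,tn,fp Confusion counts (positives on the task's positive
#'   class).
#' @return A tibble with `acc`, `sen`, `spe`.
#' @export
confusion_metrics <- function(tp, fn, tn, fp) {
  tibble::tibble(acc = (tp + tn) / (tp + fn + tn + fp),
                 sen = tp / (tp + fn),
                 spe = tn / (tn + fp))
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> %s: ACC=%.3f SEN=%.3f SPE=%.3f AUC=%s\n",
              x$task, x$acc, x$sen, x$spe,
              ifelse(is.na(x$auc), "NA", sprintf("%.3f", x$auc))))
  print(x$confusion)
  invisible(x)
}

#' Benchmark optimizers on one diagnosis task
#'
#' Splits the cohort subject-wise, trains one model per optimizer from
#' identical initial weights and identical data order, and reports each
#' optimizer's test metrics plus the first epoch at which its validation
#' accuracy reached `threshold`.
#'
#' @param cohort A cohort containing the task's classes.
#' @param task Task name.
#' @param optimizers Character vector of at least two of `"samd"`,
#'   `"sgd"`, `"adam"`, `"wobmd"`.
#' @param config A [train_config()] (its `optimizer` field is overridden
#'   per run).
#' @param split A [split_spec()].
#' @param threshold Validation-accuracy threshold for `epochs_to_threshold`.
#' @return A tibble with one row per optimizer: `optimizer`, `acc`, `sen`,
#'   `spe`, `auc`, `epochs_to_threshold` (NA if never reached) and
#'   `final_val_acc`.
#' @export
optimizer_benchmark <- function(cohort, task, optimizers, config,
                                split = split_spec(seed = config$seed),
                                threshold = 0.85) {
  if (length(optimizers) < 2) {
    stop("at least two optimizers are required", call. = FALSE)
  }
  parts <- subject_split(cohort, split)
  side <- dim(cohort$samples[[1]]$voxels)[1]
  model0 <- build_arcnn(arcnn_spec_scaled(input_side = side),
                        seed = config$seed)
  rows <- lapply(optimizers, function(opt) {
    cfg <- config
    cfg$task <- task
    cfg$optimizer <- opt
    fit <- train_model(model0, list(train = parts$train, val = parts$val),
                       cfg)
    rep <- evaluate(fit, parts$test, task)
    hit <- which(fit$curves$val_acc >= threshold)
    tibble::tibble(optimizer = opt, acc = rep$acc, sen = rep$sen,
                   spe = rep$spe, auc = rep$auc,
                   epochs_to_threshold = if (length(hit)) min(hit)
                                         else NA_integer_,
                   final_val_acc = if (nrow(fit$curves))
                     fit$curves$val_acc[nrow(fit$curves)] else NA_real_)
  })
  do.call(rbind, rows)
}

#' Write a benchmark table as delimited text
#'
#' @param table A tibble (e.g. from [optimizer_benchmark()]).
#' @param path Output path (tab-separated).
#' @return `path`, invisibly.
#' @export
write_benchmark <- function(table, path) {
  utils::write.table(table, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
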