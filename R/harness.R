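# Training and evaluation harness: subject-wise splitting, the optimizer
# protocol, accuracy metrics, AAMI/BHS grading and ablation runners.

#' Training configuration
#'
#' AdamW with decoupled weight decay, cosine-annealing learning-rate
#' schedule, early stopping on validation loss with best-weight restoration.
#'
#' @param lr initial learning rate.
#' @param weight_decay AdamW weight decay.
#' @param batch_size minibatch size.
#' @param max_epochs epoch budget.
#' @param patience early-stopping patience (must be below `max_epochs`).
#' @param rng_seed seed for shuffling and dropout.
#' @export
train_config <- function(lr = 1e-3, weight_decay = 1e-5, batch_size = 32L,
                         max_epochs = 120L, patience = 20L, rng_seed = 1L) {
  stopifnot(lr > 0, patience < max_epochs, batch_size >= 1)
  structure(list(lr = lr, weight_decay = weight_decay,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience), rng_seed = rng_seed),
            class = "train_config")
}

#' Split a dataset by subject
#'
#' Subjects (never windows) are shuffled and partitioned with
#' largest-remainder rounding of the ratios, so the three subject sets are
#' pairwise disjoint and every subject's windows land in exactly one split.
#'
#' @param ds an `rpw_dataset`.
#' @param ratios train/val/test proportions (sum 1).
#' @param rng_seed shuffle seed.
#' @return list with `train`, `val`, `test` datasets (split recorded in the
#'   `"split"` attribute) and `subjects`, the per-split subject ids.
#' @export
split_by_subject <- function(ds, ratios = c(0.7, 0.1, 0.2), rng_seed = 1L) {
  subs <- unique(ds$subject)
  if (length(subs) < 3) stop("need at least 3 subjects for a subject-wise split")
  stopifnot(abs(sum(ratios) - 1) < 1e-9)
  S <- length(subs)
  base <- floor(ratios * S)
  rem <- S - sum(base)
  if (rem > 0) {
    frac <- ratios * S - base
    add <- order(frac, decreasing = TRUE)[seq_len(rem)]
    base[add] <- base[add] + 1L
  }
  perm <- local_seed(rng_seed, sample(subs))
  groups <- list(train = perm[seq_len(base[1])],
                 val = if (base[2] > 0) perm[base[1] + seq_len(base[2])] else integer(0),
                 test = if (base[3] > 0) perm[base[1] + base[2] + seq_len(base[3])] else integer(0))
  out <- lapply(names(groups), function(nm) {
    d <- dataset_subset(ds, ds$subject %in% groups[[nm]])
    attr(d, "split") <- nm
    d
  })
  names(out) <- names(groups)
  out$subjects <- groups
  out
}

#' Train a MARU-MTL model
#'
#' Runs AdamW (decoupled weight decay) with a cosine-annealed learning rate,
#' records per-epoch training and validation losses, early-stops when the
#' validation loss has not improved for `patience` epochs, and restores the
#' best-validation weights.
#'
#' @param model a `maru_model`; windows are resampled to the model input
#'   length if needed.
#' @param data list with `train` and `val` datasets (SQI screening and
#'   augmentation, when used, must already have been applied to the training
#'   split only).
#' @param train_cfg a [train_config()].
#' @param loss_cfg a [loss_config()].
#' @param verbose print per-epoch losses.
#' @return list with `model` (best weights restored), `history` data frame,
#'   and `best_epoch`.
#' @export
train_model <- function(model, data, train_cfg = train_config(),
                        loss_cfg = loss_config(), verbose = FALSE) {
  tr <- data$train
  if (is.null(tr) || dataset_size(tr) == 0) stop("empty training split")
  va <- data$val
  cfg <- model$cfg
  prep <- function(ds) {
    rpw <- resample_windows(ds$rpw, cfg$input_len)
    abp <- resample_windows(ds$abp, cfg$input_len)
    list(X = model_input_batch(rpw, ds$fs), abp = abp,
         sbp = ds$sbp, dbp = ds$dbp,
         w = ds$weight %||% rep(1, dataset_size(ds)), n = dataset_size(ds))
  }
  trd <- prep(tr)
  vad <- if (!is.null(va) && dataset_size(va) > 0) prep(va) else NULL
  params <- maru_collect_params(model)
  opt <- optim_adamw(params, lr = train_cfg$lr, weight_decay = train_cfg$weight_decay)
  sched <- lr_cosine(train_cfg$lr, train_cfg$max_epochs)
  history <- data.frame()
  best <- list(loss = Inf, state = NULL, epoch = 0L)
  stall <- 0L
  local_seed(train_cfg$rng_seed, {
    for (ep in seq_len(train_cfg$max_epochs)) {
      lr_ep <- sched(ep)
      ord <- sample.int(trd$n)
      tot <- 0; nb <- 0L
      for (b0 in seq(1L, trd$n, by = train_cfg$batch_size)) {
        bi <- ord[b0:min(trd$n, b0 + train_cfg$batch_size - 1L)]
        out <- maru_forward(model, trd$X[, bi, , drop = FALSE], training = TRUE)
        ls <- total_loss_node(out, list(sbp = trd$sbp[bi], dbp = trd$dbp[bi],
                                        abp = trd$abp[bi, , drop = FALSE]),
                              loss_cfg, trd$w[bi])
        ag_zero_grad(params)
        ag_backward(ls$total)
        opt$step(lr_ep)
        tot <- tot + ag_val(ls$total); nb <- nb + 1L
      }
      vl <- if (is.null(vad)) tot / nb else eval_loss(model, vad, loss_cfg)
      history <- rbind(history, data.frame(epoch = ep, lr = lr_ep,
                                           train_loss = tot / nb, val_loss = vl,
                                           best_val = min(vl, best$loss)))
      if (verbose) message(sprintf("epoch %3d lr %.2e train %.4f val %.4f",
                                   ep, lr_ep, tot / nb, vl))
      if (vl < best$loss - 1e-9) {
        best <- list(loss = vl, state = lapply(maru_modules(model), nn_state),
                     epoch = ep)
        stall <- 0L
      } else {
        stall <- stall + 1L
        if (stall >= train_cfg$patience) break
      }
    }
  })
  if (!is.null(best$state)) {
    ms <- maru_modules(model)
    for (i in seq_along(ms)) nn_load_state(ms[[i]], best$state[[i]])
  }
  model$trained_on <- unique(tr$subject)
  list(model = model, history = history, best_epoch = best$epoch)
}

eval_loss <- function(model, prepped, loss_cfg, batch_size = 64L) {
  tot <- 0; n <- prepped$n
  for (b0 in seq(1L, n, by = batch_size)) {
    bi <- b0:min(n, b0 + batch_size - 1L)
    out <- maru_forward(model, prepped$X[, bi, , drop = FALSE], training = FALSE)
    bp <- ag_val(out$bp)
    ls <- total_loss(list(sbp = bp[, 1], dbp = bp[, 2],
                          abp = ag_val(out$abp)[1L, , , drop = TRUE]),
                     list(sbp = prepped$sbp[bi], dbp = prepped$dbp[bi],
                          abp = prepped$abp[bi, , drop = FALSE]),
                     loss_cfg, prepped$w[bi])
    tot <- tot + ls$total * length(bi)
  }
  tot / n
}

#' Resample windows to a target length by linear interpolation
#' @param m `N x L` matrix (or vector).
#' @param L_out target length.
#' @export
resample_windows <- function(m, L_out) {
  if (is.null(dim(m))) m <- matrix(m, 1L)
  L <- ncol(m)
  if (L == L_out) return(m)
  xout <- seq(1, L, length.out = L_out)
  t(apply(m, 1, function(r) stats::approx(seq_len(L), r, xout = xout)$y))
}

#' Per-target error metrics
#'
#' Error convention: predicted minus reference. `SD` is the sample standard
#' deviation of the errors; the Pearson correlation of a constant prediction
#' is undefined and reported as `NaN` with a warning.
#'
#' @param pred,ref numeric vectors, mmHg.
#' @return list with `me`, `sd`, `mae`, `rmse`, `r`, `pct5`, `pct10`,
#'   `pct15`, `n`.
#' @export
bp_metrics <- function(pred, ref) {
  if (length(pred) < 2) stop("need at least 2 windows (SD undefined otherwise)")
  e <- pred - ref
  r <- if (stats::sd(pred) < 1e-12 || stats::sd(ref) < 1e-12) {
    warning("constant prediction or reference: Pearson r undefined")
    NaN
  } else stats::cor(pred, ref)
  list(me = mean(e), sd = stats::sd(e), mae = mean(abs(e)),
       rmse = sqrt(mean(e^2)), r = r,
       pct5 = 100 * mean(abs(e) <= 5), pct10 = 100 * mean(abs(e) <= 10),
       pct15 = 100 * mean(abs(e) <= 15), n = length(e))
}

#' AAMI accuracy criterion
#'
#' Pass when `|ME| <= 5` mmHg and `SD <= 8` mmHg (boundaries inclusive).
#'
#' @param me,sd mean error and error standard deviation, mmHg.
#' @export
aami_check <- function(me, sd) {
  stopifnot(is.finite(me), is.finite(sd))
  abs(me) <= 5 && sd <= 8
}

#' BHS cumulative-error grade
#'
#' Grade A requires at least 60/85/95 percent of absolute errors within
#' 5/10/15 mmHg, grade B 50/75/90, grade C 40/65/85 (boundaries inclusive);
#' otherwise D.
#'
#' @param pct5,pct10,pct15 cumulative percentages.
#' @export
bhs_grade <- function(pct5, pct10, pct15) {
  stopifnot(pct5 >= 0, pct5 <= pct10, pct10 <= pct15, pct15 <= 100)
  thr <- list(A = c(60, 85, 95), B = c(50, 75, 90), C = c(40, 65, 85))
  for (g in names(thr)) {
    t <- thr[[g]]
    if (pct5 >= t[1] && pct10 >= t[2] && pct15 >= t[3]) return(g)
  }
  "D"
}

#' Bland-Altman agreement summary
#' @param pred,ref numeric vectors, mmHg.
#' @return list with `bias` and `loa` (bias +/- 1.96 SD).
#' @export
bland_altman <- function(pred, ref) {
  e <- pred - ref
  b <- mean(e)
  s <- stats::sd(e)
  list(bias = b, loa = c(lower = b - 1.96 * s, upper = b + 1.96 * s))
}

#' Evaluate a trained model on a test split
#'
#' @param model trained `maru_model`.
#' @param test_ds test dataset (already SQI-screened when screening is part
#'   of the protocol).
#' @return `metrics_report` list: per-target metrics, AAMI flags, BHS
#'   grades, Bland-Altman summaries, per-subject MAE and correlation.
#' @export
evaluate_model <- function(model, test_ds) {
  if (dataset_size(test_ds) < 2) stop("need at least 2 test windows")
  rpw <- resample_windows(test_ds$rpw, model$cfg$input_len)
  pr <- maru_predict(model, rpw, fs = test_ds$fs)
  report_metrics(pr$sbp, test_ds$sbp, pr$dbp, test_ds$dbp, test_ds$subject)
}

#' Assemble a metrics report from paired predictions and references
#' @param sbp_pred,sbp_ref,dbp_pred,dbp_ref numeric vectors, mmHg.
#' @param subject optional per-window subject ids for the per-subject
#'   breakdown.
#' @export
report_metrics <- function(sbp_pred, sbp_ref, dbp_pred, dbp_ref, subject = NULL) {
  sbp <- bp_metrics(sbp_pred, sbp_ref)
  dbp <- bp_metrics(dbp_pred, dbp_ref)
  per_subject <- NULL
  if (!is.null(subject)) {
    per_subject <- do.call(rbind, lapply(unique(subject), function(s) {
      i <- subject == s
      data.frame(subject = s,
                 sbp_mae = mean(abs(sbp_pred[i] - sbp_ref[i])),
                 dbp_mae = mean(abs(dbp_pred[i] - dbp_ref[i])),
                 sbp_r = if (sum(i) > 2 && stats::sd(sbp_ref[i]) > 1e-12 &&
                             stats::sd(sbp_pred[i]) > 1e-12)
                   stats::cor(sbp_pred[i], sbp_ref[i]) else NA_real_,
                 dbp_r = if (sum(i) > 2 && stats::sd(dbp_ref[i]) > 1e-12 &&
                             stats::sd(dbp_pred[i]) > 1e-12)
                   stats::cor(dbp_pred[i], dbp_ref[i]) else NA_real_)
    }))
  }
  structure(list(
    sbp = sbp, dbp = dbp,
    aami = list(sbp = aami_check(sbp$me, sbp$sd), dbp = aami_check(dbp$me, dbp$sd)),
    bhs = list(sbp = bhs_grade(sbp$pct5, sbp$pct10, sbp$pct15),
               dbp = bhs_grade(dbp$pct5, dbp$pct10, dbp$pct15)),
    bland_altman = list(sbp = bland_altman(sbp_pred, sbp_ref),
                        dbp = bland_altman(dbp_pred, dbp_ref)),
    per_subject = per_subject), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  f <- function(t, m) sprintf(
    "%s: ME %.2f SD %.2f MAE %.2f RMSE %.2f r %.3f | <=5/10/15 mmHg: %.1f/%.1f/%.1f%% | AAMI %s BHS %s",
    t, m$me, m$sd, m$mae, m$rmse, m$r, m$pct5, m$pct10, m$pct15,
    ifelse(x$aami[[tolower(t)]], "pass", "fail"), x$bhs[[tolower(t)]])
  cat(f("SBP", x$sbp), "\n")
  cat(f("DBP", x$dbp), "\n")
  invisible(x)
}

#' Run an ablation suite on synthetic data
#'
#' Trains one tiny model per variant under an identical subject split, seed
#' and optimizer configuration, differing only in the ablated component, and
#' reports per-variant test metrics.
#'
#' @param suite one of `"lambda_sweep"` (auxiliary loss weight in 0, 0.01,
#'   0.05, 0.1, 0.2, 0.5), `"sqi_retention"` (retention 1.0, 0.9, 0.8, 0.7),
#'   `"bottleneck_variant"` (single-scale, multi-scale, multi-scale + CTA)
#'   or `"temporal_module"` (convolution-only vs bidirectional Mamba).
#' @param splits subject-wise splits from [split_by_subject()].
#' @param model_cfg base [model_config()] (tiny recommended).
#' @param train_cfg a [train_config()] shared by all variants.
#' @param loss_cfg base [loss_config()].
#' @param vae fitted quality scorer; required for `"sqi_retention"`.
#' @param rng_seed model-initialization seed shared by all variants.
#' @return data frame with one row per variant; the shared split is attached
#'   as attribute `"subjects"`.
#' @export
run_ablation <- function(suite = c("lambda_sweep", "sqi_retention",
                                   "bottleneck_variant", "temporal_module"),
                         splits, model_cfg = model_config("tiny"),
                         train_cfg = train_config(max_epochs = 10L, patience = 5L),
                         loss_cfg = loss_config(), vae = NULL, rng_seed = 1L) {
  suite <- match.arg(suite)
  run_variant <- function(label, data, mcfg = model_cfg, lcfg = loss_cfg) {
    model <- maru_model(mcfg, rng_seed = rng_seed)
    fit <- train_model(model, data, train_cfg, lcfg)
    rep <- evaluate_model(fit$model, data$test)
    data.frame(variant = label,
               sbp_mae = rep$sbp$mae, sbp_sd = rep$sbp$sd, sbp_r = rep$sbp$r,
               sbp_bhs = rep$bhs$sbp, dbp_mae = rep$dbp$mae,
               dbp_sd = rep$dbp$sd, dbp_r = rep$dbp$r, dbp_bhs = rep$bhs$dbp,
               aami = rep$aami$sbp && rep$aami$dbp)
  }
  base_data <- list(train = splits$train, val = splits$val, test = splits$test)
  rows <- switch(suite,
    lambda_sweep = lapply(c(0, 0.01, 0.05, 0.1, 0.2, 0.5), function(lam)
      run_variant(paste0("lambda=", lam), base_data,
                  lcfg = loss_config(loss_cfg$lambda_sbp, lam, loss_cfg$delta))),
    sqi_retention = {
      if (is.null(vae)) stop("sqi_retention ablation needs a fitted quality scorer")
      lapply(c(1.0, 0.9, 0.8, 0.7), function(rf) {
        scr <- screen_dataset(splits, vae, retain_fraction = rf)
        run_variant(paste0("retention=", rf),
                    list(train = scr$train, val = scr$val, test = scr$test))
      })
    },
    bottleneck_variant = lapply(c("single", "multiscale", "multiscale_cta"),
      function(bv) {
        mc <- model_cfg
        mc$bottleneck_variant <- bv
        run_variant(paste0("bottleneck=", bv), base_data, mcfg = mc)
      }),
    temporal_module = lapply(c("none", "bimamba"), function(tm) {
      mc <- model_cfg
      mc$temporal_module <- tm
      run_variant(paste0("temporal=", tm), base_data, mcfg = mc)
    }))
  out <- do.call(rbind, rows)
  attr(out, "subjects") <- splits$subjects
  out
}
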