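# The three-stage alternating training loop: Stage 1 explores random masks
# to teach the Selector the mask -> validation-loss landscape, Stage 2
# exploits the Selector's input gradients to focus on a top-Nf subspace, and
# Stage 3 refines the Classifier with the best recorded mask frozen.

#' Training configuration
#'
#' @param E1 Stage-1 (exploration) epochs; 0 disables Stage 1 (used for
#'   ablation studies).
#' @param E2,E3 Stage-2 (exploitation) and Stage-3 (refinement) epochs;
#'   `E2 + E3 = 100` by default.
#' @param N_f Maximum number of selected feature matrices (2 to 5 by
#'   convention).
#' @param C Candidate combinations sampled per Stage-2 epoch when the
#'   subset lattice of the top-`N_f` matrices is too large to enumerate.
#' @param seed Master seed fixing mask sampling and both model
#'   initializations.
#' @param patience Stage-3 early-stopping patience on validation Fmax.
#' @param d_c Classifier branch/head width.
#' @param selector_hidden Selector hidden width.
#' @param lr_classifier,lr_selector Adam learning rates.
#' @param classifier_wd Classifier weight-decay coefficient.
#' @param selector_window Number of most-recent record pairs the Selector is
#'   refit on each epoch (see [selector_update()]).
#' @param selector_steps Full-batch gradient steps per Selector refit.
#' @param selector_wd Selector weight-decay coefficient.
#' @param loss A [loss_config()].
#' @param record_scope `"stage2"` (default) picks the best mask over the
#'   Stage-2 record, where candidate masks are evaluated against a
#'   near-converged Classifier; `"all"` also admits Stage-1 entries, whose
#'   losses come from a still-drifting Classifier.
#' @return An object of class `train_config`.
#' @export
train_config <- function(E1 = 100, E2 = 50, E3 = 50, N_f = 2, C = 20,
                         seed = 1, patience = 10, d_c = 64,
                         selector_hidden = 32, lr_classifier = 3e-3,
                         classifier_wd = 0,
                         lr_selector = 1e-3, selector_window = 50,
                         selector_steps = 20, selector_wd = 1e-2,
                         loss = loss_config(),
                         record_scope = c("stage2", "all")) {
  record_scope <- match.arg(record_scope)
  stopifnot(E1 >= 0, E2 >= 1, E3 >= 0, N_f >= 1, C >= 1, patience >= 1,
            selector_window >= 1, selector_steps >= 1, selector_wd >= 0)
  structure(list(E1 = as.integer(E1), E2 = as.integer(E2), E3 = as.integer(E3),
                 N_f = as.integer(N_f), C = as.integer(C),
                 seed = as.integer(seed), patience = as.integer(patience),
                 d_c = as.integer(d_c),
                 selector_hidden = as.integer(selector_hidden),
                 lr_classifier = lr_classifier, lr_selector = lr_selector,
                 classifier_wd = classifier_wd,
                 selector_window = as.integer(selector_window),
                 selector_steps = as.integer(selector_steps),
                 selector_wd = selector_wd,
                 loss = loss, record_scope = record_scope),
            class = "train_config")
}

#' Sample a random mask with bounded popcount
#'
#' Draws a popcount uniformly from `1..N_f`, then that many positions
#' uniformly without replacement, so every mask with `1 <= popcount <= N_f`
#' has positive probability.
#'
#' @param m Mask length (number of feature matrices).
#' @param N_f Maximum popcount.
#' @return Binary integer vector of length `m`.
#' @export
sample_mask <- function(m, N_f) {
  stopifnot(N_f >= 1, N_f <= m)
  k <- sample.int(N_f, 1)
  mask <- integer(m)
  mask[sample.int(m, k)] <- 1L
  mask
}

mask_string <- function(mask) paste(mask, collapse = "")

record_entry <- function(stage, epoch, mask, loss, selector_mse = NA_real_,
                         val_fmax = NA_real_) {
  data.frame(stage = stage, epoch = epoch, mask = mask_string(mask),
             loss = loss, selector_mse = selector_mse, val_fmax = val_fmax,
             stringsAsFactors = FALSE)
}

# internal: validation ASL loss of the classifier under a mask, forward-only
val_loss <- function(space, labels, mask, classifier, rows_val, loss_cfg) {
  p <- classifier_forward(space, mask, classifier, rows = rows_val)
  asl_loss(p, labels$y$val, loss_cfg)
}

#' One Stage-1 (exploration) epoch
#'
#' Samples a random mask `m1`, takes one Classifier training step on the
#' training split, evaluates the updated Classifier on the validation split
#' (loss `L_c`), appends `(m1, L_c)` to the Selector's training history and
#' refits the Selector on the most recent window of that history.
#'
#' @param space A [feature_space()].
#' @param labels A [label_matrix()] (splits must name rows of the space).
#' @param classifier,selector Current models.
#' @param cfg A [train_config()].
#' @param rows Named list of integer row indices per split (internal
#'   callers precompute this; see [run_dual_training()]).
#' @param history List with `masks` (list of mask vectors) and `losses`
#'   (numeric): the Selector's accumulated training pairs. NULL starts an
#'   empty history.
#' @return List with updated `classifier`, `selector`, `history`, the mask,
#'   `L_c` and a one-row `record` entry.
#' @export
stage1_epoch <- function(space, labels, classifier, selector, cfg, rows,
                         history = NULL) {
  mask <- sample_mask(length(space), cfg$N_f)
  st <- classifier_train_step(space, mask, classifier, labels$y$train,
                              rows = rows$train, loss_cfg = cfg$loss,
                              lr = cfg$lr_classifier,
                              weight_decay = cfg$classifier_wd)
  classifier <- st$model
  L_c <- val_loss(space, labels, mask, classifier, rows$val, cfg$loss)
  if (!is.finite(L_c)) stop("non-finite validation loss in Stage 1 (mask ",
                            mask_string(mask), ")")
  history <- history_append(history, mask, L_c)
  sf <- selector_refit(selector, history, cfg)
  list(classifier = classifier, selector = sf$model, history = history,
       mask = mask, L_c = L_c,
       record = record_entry("stage1", NA_integer_, mask, L_c, sf$mse))
}

history_append <- function(history, mask, loss) {
  if (is.null(history)) history <- list(masks = list(), losses = numeric(0))
  history$masks[[length(history$masks) + 1L]] <- mask
  history$losses <- c(history$losses, loss)
  history
}

selector_refit <- function(selector, history, cfg) {
  n <- length(history$losses)
  keep <- max(1L, n - cfg$selector_window + 1L):n
  selector_update(selector, history$masks[keep], history$losses[keep],
                  lr = cfg$lr_selector, weight_decay = cfg$selector_wd,
                  steps = cfg$selector_steps)
}

# all non-empty subsets of idx as masks of length m
subset_masks <- function(idx, m) {
  k <- length(idx)
  out <- vector("list", 2^k - 1)
  for (code in seq_len(2^k - 1)) {
    take <- idx[bitwAnd(code, bitwShiftL(1L, seq_len(k) - 1L)) > 0]
    mask <- integer(m)
    mask[take] <- 1L
    out[[code]] <- mask
  }
  out
}

#' One Stage-2 (exploitation) epoch
#'
#' Scores matrix importance as the Selector's absolute input gradients at
#' the all-0.5 probe, keeps the top-`N_f` matrices (ties broken toward the
#' lower index), evaluates candidate subsets of that subspace forward-only
#' on the validation split (all non-empty subsets when there are at most 31,
#' otherwise `C` uniform draws), uses the argmin mask `m2` for one
#' Classifier training step, and refits the Selector with `(m2, L_c)`
#' appended to its history.
#'
#' @inheritParams stage1_epoch
#' @return List with updated models, `history`, `m2`, `L_c` and the
#'   candidate + final `record` entries.
#' @export
stage2_epoch <- function(space, labels, classifier, selector, cfg, rows,
                         history = NULL) {
  m <- length(space)
  imp <- gradient_importance(selector)
  top <- order(-imp, seq_len(m))[seq_len(cfg$N_f)]
  top <- sort(top)
  cands <- if (2^length(top) - 1 <= 31) {
    subset_masks(top, m)
  } else {
    lapply(seq_len(cfg$C), function(i) {
      k <- sample.int(length(top), 1)
      mask <- integer(m)
      mask[sample(top, k)] <- 1L
      mask
    })
  }
  losses <- vapply(cands, function(mk) {
    val_loss(space, labels, mk, classifier, rows$val, cfg$loss)
  }, numeric(1))
  recs <- do.call(rbind, lapply(seq_along(cands), function(i) {
    record_entry("stage2_candidate", NA_integer_, cands[[i]], losses[i])
  }))
  m2 <- cands[[which.min(losses)]]
  st <- classifier_train_step(space, m2, classifier, labels$y$train,
                              rows = rows$train, loss_cfg = cfg$loss,
                              lr = cfg$lr_classifier,
                              weight_decay = cfg$classifier_wd)
  classifier <- st$model
  L_c <- val_loss(space, labels, m2, classifier, rows$val, cfg$loss)
  if (!is.finite(L_c)) stop("non-finite validation loss in Stage 2")
  history <- history_append(history, m2, L_c)
  sf <- selector_refit(selector, history, cfg)
  recs <- rbind(recs, record_entry("stage2", NA_integer_, m2, L_c, sf$mse))
  list(classifier = classifier, selector = sf$model, history = history,
       m2 = m2, L_c = L_c, record = recs)
}

#' Stage-3 refinement with a frozen mask
#'
#' Trains only the branches selected by `m_star` and the prediction head for
#' up to `E3` epochs with early stopping on validation Fmax; parameters of
#' unselected branches are untouched. Returns test-split scores from the
#' checkpoint with the best validation Fmax.
#'
#' @inheritParams stage1_epoch
#' @param m_star The frozen mask (the record argmin).
#' @param E3 Maximum refinement epochs; 0 evaluates the incoming Classifier
#'   once.
#' @param patience Early-stopping patience (epochs without validation-Fmax
#'   improvement).
#' @return List with the refined `classifier`, `scores_test`, `scores_val`,
#'   `best_epoch`, and the per-epoch `fmax_trace`.
#' @export
stage3_train <- function(space, labels, classifier, m_star, cfg, rows,
                         E3 = cfg$E3, patience = cfg$patience) {
  best <- classifier
  p_val <- classifier_forward(space, m_star, classifier, rows = rows$val)
  best_fmax <- fmax(p_val, labels$y$val)$fmax
  best_epoch <- 0L
  trace <- best_fmax
  wait <- 0L
  if (E3 > 0) {
    for (ep in seq_len(E3)) {
      st <- classifier_train_step(space, m_star, classifier, labels$y$train,
                                  rows = rows$train, loss_cfg = cfg$loss,
                                  lr = cfg$lr_classifier,
                                  weight_decay = cfg$classifier_wd)
      classifier <- st$model
      p_val <- classifier_forward(space, m_star, classifier, rows = rows$val)
      fm <- fmax(p_val, labels$y$val)$fmax
      trace <- c(trace, fm)
      if (fm > best_fmax) {
        best_fmax <- fm
        best <- classifier
        best_epoch <- ep
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= patience) break
      }
    }
  }
  list(classifier = best,
       scores_test = classifier_forward(space, m_star, best, rows = rows$test),
       scores_val = classifier_forward(space, m_star, best, rows = rows$val),
       best_epoch = best_epoch, fmax_trace = trace)
}

space_split_rows <- function(space, labels) {
  mats <- space_matrices(space)
  rn <- rownames(mats[[1]])
  if (is.null(rn)) {
    # unnamed rows: splits must be integer indices already
    stop("feature matrices must carry protein rownames matching the label splits")
  }
  lapply(labels$splits, function(ids) {
    pos <- match(ids, rn)
    if (anyNA(pos)) stop("label split names proteins absent from the feature space")
    pos
  })
}

#' Run the full three-stage dual-network training
#'
#' Executes Stage 1 for `E1` epochs, Stage 2 for `E2` epochs, identifies
#' `m*` as the mask with the minimal recorded validation loss (earliest
#' entry on ties), and refines with Stage 3. The master seed fixes the mask
#' sequence and both model initializations, so runs are reproducible.
#'
#' @param space A [feature_space()] whose matrices have protein rownames.
#' @param labels A [label_matrix()] over the same proteins.
#' @param cfg A [train_config()].
#' @return An object of class `dualnet_fit`: `m_star`, `classifier`,
#'   `selector`, `eval` (test-split [evaluate_predictions()] at the
#'   validation threshold), `record`, `tau_val`, `best_epoch`, `config`.
#' @export
run_dual_training <- function(space, labels, cfg = train_config()) {
  stopifnot(inherits(cfg, "train_config"))
  if (length(space) < 2) stop("the feature space must contain at least 2 matrices")
  if (cfg$N_f > length(space)) stop("N_f exceeds the number of feature matrices")
  rows <- space_split_rows(space, labels)
  set.seed(cfg$seed)
  d_fs <- vapply(space_matrices(space), ncol, integer(1))
  classifier <- classifier_init(d_fs, K = length(labels$terms), d_c = cfg$d_c,
                                seed = cfg$seed)
  selector <- selector_init(length(space), d_hidden = cfg$selector_hidden,
                            seed = cfg$seed + 1L)
  record <- NULL
  history <- NULL
  for (ep in seq_len(cfg$E1)) {
    s1 <- stage1_epoch(space, labels, classifier, selector, cfg, rows, history)
    classifier <- s1$classifier; selector <- s1$selector; history <- s1$history
    s1$record$epoch <- ep
    record <- rbind(record, s1$record)
  }
  for (ep in seq_len(cfg$E2)) {
    s2 <- stage2_epoch(space, labels, classifier, selector, cfg, rows, history)
    classifier <- s2$classifier; selector <- s2$selector; history <- s2$history
    s2$record$epoch <- cfg$E1 + ep
    record <- rbind(record, s2$record)
  }
  scope <- if (cfg$record_scope == "all") rep(TRUE, nrow(record)) else
    record$stage != "stage1"
  idx <- which(scope)[which.min(record$loss[scope])]
  m_star <- as.integer(strsplit(record$mask[idx], "")[[1]])
  s3 <- stage3_train(space, labels, classifier, m_star, cfg, rows)
  tau_val <- fmax(s3$scores_val, labels$y$val)$tau_star
  ev <- evaluate_predictions(s3$scores_test, labels$y$test, tau = tau_val)
  structure(list(m_star = m_star, classifier = s3$classifier,
                 selector = selector, eval = ev, record = record,
                 tau_val = tau_val, best_epoch = s3$best_epoch,
                 fmax_trace = s3$fmax_trace, config = cfg,
                 sources = if (inherits(space, "feature_space")) space$sources
                           else NULL),
            class = "dualnet_fit")
}

#' @export
print.dualnet_fit <- function(x, ...) {
  sel <- which(x$m_star == 1)
  lab <- if (!is.null(x$sources)) paste(x$sources[sel], collapse = ", ") else
    paste(sel, collapse = ", ")
  cat("dualnet_fit\n  m* =", mask_string(x$m_star), "(", lab, ")\n")
  cat("  test:")
  print(x$eval)
  invisible(x)
}

#' Train the Classifier with a fixed mask (no Selector)
#'
#' Baseline used by the ablation studies: the Classifier is trained for
#' `epochs` epochs with the given mask always selected, with the same
#' checkpointing-on-validation-Fmax rule as Stage 3.
#'
#' @inheritParams run_dual_training
#' @param mask Fixed binary mask (default: all matrices selected).
#' @param epochs Training epochs (default `E1 + E2 + E3`).
#' @return A `dualnet_fit`-like list with `m_star = mask` and `eval`.
#' @export
run_fixed_mask_training <- function(space, labels, cfg = train_config(),
                                    mask = rep(1L, length(space)),
                                    epochs = cfg$E1 + cfg$E2 + cfg$E3) {
  rows <- space_split_rows(space, labels)
  check_mask(mask, length(space))
  set.seed(cfg$seed)
  d_fs <- vapply(space_matrices(space), ncol, integer(1))
  classifier <- classifier_init(d_fs, K = length(labels$terms), d_c = cfg$d_c,
                                seed = cfg$seed)
  s3 <- stage3_train(space, labels, classifier, mask, cfg, rows,
                     E3 = epochs, patience = epochs + 1L)
  tau_val <- fmax(s3$scores_val, labels$y$val)$tau_star
  ev <- evaluate_predictions(s3$scores_test, labels$y$test, tau = tau_val)
  structure(list(m_star = mask, classifier = s3$classifier, selector = NULL,
                 eval = ev, record = NULL, tau_val = tau_val,
                 best_epoch = s3$best_epoch, fmax_trace = s3$fmax_trace,
                 config = cfg,
                 sources = if (inherits(space, "feature_space")) space$sources
                           else NULL),
            class = "dualnet_fit")
}

#' Write the per-epoch training record as JSON lines
#'
#' @param fit A [run_dual_training()] result.
#' @param path Output path (one JSON object per line).
#' @return `path`, invisibly.
#' @export
write_train_record <- function(fit, path) {
  stopifnot(inherits(fit, "dualnet_fit"))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(fit$record))) {
    writeLines(jsonlite::toJSON(as.list(fit$record[i, ]), auto_unbox = TRUE,
                                digits = NA, na = "null"), con)
  }
  invisible(path)
}
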