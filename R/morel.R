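# Multi-output regression and learning (MOREL) for systematic,
# group-specific missingness: CpGs observed in both groups are the
# training instances; a direction-specific model maps the source group's
# beta vector at a CpG to the target group's beta vector.

#' Configuration of a MOREL learner
#'
#' @param learner one of `"rf"` (random forest, one forest per target
#'   sample), `"svr"` (linear support vector regression, one model per
#'   target sample), `"knn"` (natively multi-target nearest neighbours)
#'   or `"dnn"` (a single network with one ReLU hidden layer sized by
#'   [dnn_hidden_units()] and a linear output layer).
#' @param n_trees forest size for `"rf"` (default 100)
#' @param k neighbours for `"knn"` (default 5, distance-unweighted)
#' @param weighted inverse-distance weighting for `"knn"`
#' @param cost L2-regularization constant C for `"svr"` (default 1)
#' @param epsilon epsilon-insensitive zone for `"svr"` (default 0)
#' @param epochs,batch_size,learning_rate training regime for `"dnn"`
#'   (defaults 100, 256, 1e-3; squared-error loss, Adam)
#' @param seed integer seed fixed before any stochastic step
#' @return list of class `MorelConfig`
#' @export
morel_config <- function(learner = c("rf", "svr", "knn", "dnn"),
                         n_trees = 100L, k = 5L, weighted = FALSE,
                         cost = 1, epsilon = 0,
                         epochs = 100L, batch_size = 256L,
                         learning_rate = 1e-3, seed = 1L) {
  learner <- match.arg(learner)
  structure(list(learner = learner, n_trees = n_trees, k = k,
                 weighted = weighted, cost = cost, epsilon = epsilon,
                 epochs = epochs, batch_size = batch_size,
                 learning_rate = learning_rate, seed = seed),
            class = "MorelConfig")
}

#' Hidden-layer width of the MOREL-DNN
#'
#' The hidden layer holds the mean of the input and output widths,
#' rounded half-up, with a floor of one neuron.
#'
#' @param n_in,n_out input and output layer widths (source and target
#'   group sample counts)
#' @return integer hidden width
#' @examples
#' dnn_hidden_units(15, 15)  # 15
#' dnn_hidden_units(2, 3)    # 3
#' @export
dnn_hidden_units <- function(n_in, n_out) {
  if (n_in < 1 || n_out < 1) stopf("layer widths must be >= 1")
  max(1L, as.integer(floor((n_in + n_out) / 2 + 0.5)))
}

#' Assemble the training matrices for one imputation direction
#'
#' Training instances are the CpGs complete in both groups after the
#' sporadic stage: X holds their betas over the source-group samples,
#' Y over the target-group samples, in the input CpG order. Set
#' `strict = TRUE` to train only on CpGs that never had a missing value.
#'
#' @param matrix beta matrix with the sporadic stage already applied
#' @param categories a [`CategorizedSites`][categorize_cpgs]
#' @param groups a [`GroupAssignment`][assign_groups]
#' @param direction length-2 character vector `c(source, target)` of group
#'   labels
#' @param strict train only on originally non-missing CpGs
#' @return list with matrices `x`, `y` and the training CpG ids
#' @export
build_training_set <- function(matrix, categories, groups,
                               direction, strict = FALSE) {
  if (length(direction) != 2)
    stopf("direction must be c(source_label, target_label)")
  src <- group_samples(groups, direction[1])
  tgt <- group_samples(groups, direction[2])
  if (length(src) == 0 || length(tgt) == 0)
    stopf("unknown group label in direction")
  m <- unclass(matrix)
  pool <- if (strict) categories$non_missing
          else union(categories$non_missing, categories$sporadic)
  rows <- rownames(m)[rownames(m) %in% pool]
  complete <- rowSums(is.na(m[rows, c(src, tgt), drop = FALSE])) == 0
  rows <- rows[complete]
  if (length(rows) == 0)
    stopf("no complete training CpG; run the sporadic stage first")
  list(x = m[rows, src, drop = FALSE],
       y = m[rows, tgt, drop = FALSE],
       cpg_ids = rows)
}

#' Fit a direction-specific multi-output model
#'
#' RF and SVR fit one independent regressor per target sample; KNN stores
#' the training matrices and averages the Y rows of the k nearest X rows;
#' DNN trains a single network (input width = source samples, one ReLU
#' hidden layer, linear output of width = target samples). All learners
#' are deterministic under the configured seed.
#'
#' @param x,y training matrices from [build_training_set()]
#' @param config a [morel_config()]
#' @return object of class `DirectionModel` with a `predict()` method
#' @export
fit_morel <- function(x, y, config = morel_config()) {
  if (nrow(x) != nrow(y)) stopf("X and Y must have equal row counts")
  need <- max(5L, if (config$learner == "knn") config$k else 0L)
  if (nrow(x) < need)
    stopf("too few training rows (%d); need >= %d", nrow(x), need)
  fit <- switch(config$learner,
    knn = list(x = x, y = y),
    rf = lapply(seq_len(ncol(y)), function(j) {
      xtr <- as.data.frame(x)
      colnames(xtr) <- paste0("v", seq_len(ncol(x)))
      ranger::ranger(x = xtr, y = y[, j], num.trees = config$n_trees,
                     seed = derive_seed(config$seed, j),
                     num.threads = 1L)
    }),
    svr = lapply(seq_len(ncol(y)), function(j)
      linsvr_fit(x, y[, j], cost = config$cost,
                 epsilon = config$epsilon)),
    dnn = mlp_fit(x, y,
                  hidden = dnn_hidden_units(ncol(x), ncol(y)),
                  epochs = config$epochs,
                  batch_size = config$batch_size,
                  learning_rate = config$learning_rate,
                  seed = config$seed))
  structure(list(learner = config$learner, fit = fit, config = config,
                 n_in = ncol(x), n_out = ncol(y),
                 source_ids = colnames(x), target_ids = colnames(y),
                 n_train = nrow(x)),
            class = "DirectionModel")
}

#' @export
print.DirectionModel <- function(x, ...) {
  cat(sprintf("DirectionModel: MOREL-%s, %d -> %d samples, %d training CpGs\n",
              toupper(x$learner), x$n_in, x$n_out, x$n_train))
  invisible(x)
}

#' Predict target-group betas from source-group betas
#'
#' @param object a [`DirectionModel`][fit_morel]
#' @param newdata matrix of source-group betas (CpGs x source samples)
#' @param ... unused
#' @return matrix of predictions (CpGs x target samples), unclipped.
#' @export
predict.DirectionModel <- function(object, newdata, ...) {
  x <- as.matrix(newdata)
  if (ncol(x) != object$n_in)
    stopf("newdata has %d columns; model expects %d", ncol(x), object$n_in)
  pred <- switch(object$learner,
    knn = knn_multi_predict(object$fit$x, object$fit$y, x,
                            k = object$config$k,
                            weighted = object$config$weighted),
    rf = {
      xte <- as.data.frame(x)
      colnames(xte) <- paste0("v", seq_len(ncol(x)))
      do.call(cbind, lapply(object$fit, function(f)
        stats::predict(f, data = xte, num.threads = 1L)$predictions))
    },
    svr = do.call(cbind, lapply(object$fit, function(f)
      cbind(1, x) %*% f)),
    dnn = mlp_predict(object$fit, x))
  dimnames(pred) <- list(rownames(x), object$target_ids)
  pred
}

knn_multi_predict <- function(xtr, ytr, xte, k = 5L, weighted = FALSE) {
  k <- min(k, nrow(xtr))
  # squared Euclidean distances via the Gram expansion
  d2 <- outer(rowSums(xte^2), rowSums(xtr^2), `+`) - 2 * xte %*% t(xtr)
  d2[d2 < 0] <- 0
  out <- array(0, dim = c(nrow(xte), ncol(ytr)))
  for (i in seq_len(nrow(xte))) {
    nb <- order(d2[i, ])[seq_len(k)]
    out[i, ] <- if (weighted) {
      w <- 1 / (sqrt(d2[i, nb]) + 1e-9)
      colSums(ytr[nb, , drop = FALSE] * w) / sum(w)
    } else colMeans(ytr[nb, , drop = FALSE])
  }
  out
}

# Linear epsilon-insensitive SVR fitted by iteratively reweighted ridge
# least squares (majorize-minimize on the smoothed hinge). At epsilon = 0
# this is L2-penalised least-absolute-deviation regression, the objective
# of a linear SVR. The intercept is unpenalised.
linsvr_fit <- function(x, y, cost = 1, epsilon = 0, delta = 1e-6,
                       max_iter = 60L) {
  xd <- cbind(1, x)
  p <- ncol(xd)
  pen <- diag(1, p); pen[1, 1] <- 0
  beta <- qr.coef(qr(xd), y)          # least-squares start
  beta[is.na(beta)] <- 0
  for (it in seq_len(max_iter)) {
    r <- as.numeric(y - xd %*% beta)
    a <- pmax(abs(r), delta)
    w <- cost * pmax(a - epsilon, 0) / (a * pmax(a - epsilon, delta))
    wx <- xd * w
    beta_new <- tryCatch(
      solve(crossprod(wx, xd) + pen, crossprod(wx, y)),
      error = function(e) beta)
    if (max(abs(beta_new - beta)) < 1e-9) { beta <- beta_new; break }
    beta <- beta_new
  }
  as.numeric(beta)
}

#' Impute systematic (group-specific) missing values
#'
#' For every A-specific CpG a model trained in the B-to-A direction
#' predicts the A-sample betas from that CpG's observed B-sample betas;
#' B-specific CpGs are handled symmetrically. Predictions are clipped to
#' \[0, 1\]; all other cells are untouched. A direction with zero
#' group-specific CpGs is skipped silently.
#'
#' @param matrix beta matrix with the sporadic stage already applied
#' @param categories a [`CategorizedSites`][categorize_cpgs]
#' @param groups a [`GroupAssignment`][assign_groups]
#' @param config a [morel_config()]
#' @param strict train only on originally non-missing CpGs
#' @return the matrix with group-specific cells filled
#' @export
impute_systematic <- function(matrix, categories, groups,
                              config = morel_config(), strict = FALSE) {
  lev <- group_levels(groups)
  m <- unclass(matrix)
  targets <- list(list(rows = categories$a_specific,
                       direction = c(lev[2], lev[1])),
                  list(rows = categories$b_specific,
                       direction = c(lev[1], lev[2])))
  for (k in seq_along(targets)) {
    rows <- targets[[k]]$rows
    if (length(rows) == 0) next
    dir <- targets[[k]]$direction
    cfg <- config
    cfg$seed <- derive_seed(config$seed, k)
    ts <- build_training_set(m, categories, groups, dir, strict = strict)
    model <- fit_morel(ts$x, ts$y, cfg)
    src <- group_samples(groups, dir[1])
    tgt <- group_samples(groups, dir[2])
    newx <- m[rows, src, drop = FALSE]
    if (anyNA(newx)) {
      warnf("residual missing source values at %d group-specific CpG(s); %s",
            sum(rowSums(is.na(newx)) > 0),
            "filled with the CpG's observed source mean before prediction")
      rm_ <- rowMeans(newx, na.rm = TRUE)
      idx <- which(is.na(newx), arr.ind = TRUE)
      newx[idx] <- rm_[idx[, 1]]
    }
    pred <- clip01(predict(model, newx))
    m[rows, tgt] <- pred
  }
  restore_beta(matrix, m)
}

#' Run the full two-stage imputation pipeline
#'
#' The four steps in order: (1) assign samples to two groups from the
#' binarized presence/absence patterns (or take `user_labels`);
#' (2) categorize CpGs into the five missingness classes; (3) fill
#' sporadic missing values (including the observed-side holes of
#' group-specific CpGs) with the chosen standard imputer, applied per
#' group side; (4) fill group-specific missing values with the configured
#' MOREL learner. Category counts are logged via `message()`.
#'
#' @param matrix a `BetaMatrix` or numeric matrix with dimnames
#' @param sporadic_method method name for [fill_sporadic()]
#' @param morel_config a [morel_config()]
#' @param user_labels optional named group labels overriding clustering
#' @param keep_all_missing keep CpGs missing everywhere (as-is) instead of
#'   dropping them
#' @param seed master seed propagated to every stochastic stage
#' @param sporadic_args list of extra arguments for the sporadic imputer
#' @return list with `matrix` (imputed), `categories`, `groups`
#' @export
impute_pipeline <- function(matrix, sporadic_method = "knn",
                            morel_config = morelimpute::morel_config(),
                            user_labels = NULL, keep_all_missing = FALSE,
                            seed = 1L, sporadic_args = list()) {
  if (ncol(matrix) < 2) stopf("need at least 2 samples")
  m <- unclass(matrix)
  if (!anyNA(m)) {
    groups <- if (!is.null(user_labels))
      assign_groups(m, user_labels = user_labels) else NULL
    cats <- structure(list(non_missing = rownames(m),
                           sporadic = character(0),
                           a_specific = character(0),
                           b_specific = character(0),
                           all_missing = character(0)),
                      class = "CategorizedSites")
    message("no missing values; matrix returned unchanged")
    return(list(matrix = matrix, categories = cats, groups = groups))
  }
  groups <- assign_groups(m, seed = derive_seed(seed, 1),
                          user_labels = user_labels)
  cats <- categorize_cpgs(m, groups)
  message(sprintf(
    "categories: non_missing=%d sporadic=%d a_specific=%d b_specific=%d all_missing=%d",
    length(cats$non_missing), length(cats$sporadic),
    length(cats$a_specific), length(cats$b_specific),
    length(cats$all_missing)))
  ann <- attr(matrix, "annotation")
  if (length(cats$all_missing) > 0 && !keep_all_missing) {
    keep <- setdiff(rownames(m), cats$all_missing)
    m <- m[keep, , drop = FALSE]
    if (!is.null(ann)) ann <- ann[ann$cpg_id %in% keep, , drop = FALSE]
    message(sprintf("dropped %d all-missing CpG(s)",
                    length(cats$all_missing)))
  }
  lev <- group_levels(groups)
  spec_rows <- list(cats$a_specific, cats$b_specific)
  for (gi in 1:2) {
    g <- lev[gi]
    cols <- group_samples(groups, g)
    skip <- union(spec_rows[[gi]], cats$all_missing)
    rows <- setdiff(rownames(m), skip)
    sub <- m[rows, cols, drop = FALSE]
    if (anyNA(sub)) {
      filled <- do.call(fill_sporadic,
                        c(list(matrix = sub, method = sporadic_method,
                               seed = derive_seed(seed, 10 + gi)),
                          sporadic_args))
      m[rows, cols] <- unclass(filled)
    }
  }
  cfg <- morel_config
  cfg$seed <- derive_seed(seed, 20)
  m <- impute_systematic(m, cats, groups, cfg)
  out <- beta_matrix(unclass(m), annotation = ann)
  list(matrix = out, categories = cats, groups = groups)
}
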