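feature_names_flavor <- function(flavor = c("full", "reduced")) {
  flavor <- match.arg(flavor)
  positions <- if (flavor == "full") 1:20 else 11:20
  onehot <- as.vector(vapply(positions, function(p) {
    as.vector(vapply(BASES, function(g) {
      paste0("p", sprintf("%02d", p), "_t", BASES, "_g", g)
    }, character(4)))
  }, character(16)))
  mm <- if (flavor == "full") c("mm_nonseed", "mm_seed") else "mm_seed"
  c(onehot, mm)
}

#' One-hot encode protospacer/guide pairs for blunt-rate regression
#'
#' Each protospacer position is represented by a 4x4 indicator matrix with
#' the protospacer base on the rows and the guide base on the columns; the
#' single set cell marks the (protospacer, guide) base pair at that
#' position. Matrices are flattened column-major (guide base outer, A < C
#' < G < T) and concatenated over positions, giving 320 binary variables
#' for the full flavor (positions 1-20) plus two mismatch-count variables
#' (`mm_nonseed`, positions 1-10; `mm_seed`, positions 11-20) -- 322
#' variables in total. The reduced flavor keeps positions 11-20 only
#' (160 indicators + `mm_seed` = 161 variables).
#'
#' @param protospacer,guide 20-nt ACGT sequences (vectors of equal
#'   length).
#' @param flavor `"full"` or `"reduced"`.
#' @return `encode_pairs()`: numeric matrix, one row per pair, with named
#'   columns; `encode_pair()`: a single named vector.
#' @export
#' @examples
#' v <- encode_pair(strrep("A", 20), strrep("A", 20))
#' length(v)  # 322
encode_pairs <- function(protospacer, guide, flavor = c("full", "reduced")) {
  flavor <- match.arg(flavor)
  assert_spacer(protospacer, "protospacer")
  assert_spacer(guide, "guide")
  n <- max(length(protospacer), length(guide))
  protospacer <- rep_len(protospacer, n)
  guide <- rep_len(guide, n)
  positions <- if (flavor == "full") 1:20 else 11:20
  tmat <- do.call(rbind, strsplit(protospacer, ""))
  gmat <- do.call(rbind, strsplit(guide, ""))
  tidx <- matrix(match(tmat, BASES), n)
  gidx <- matrix(match(gmat, BASES), n)
  X <- matrix(0, n, 16L * length(positions))
  for (k in seq_along(positions)) {
    p <- positions[k]
    col <- 16L * (k - 1L) + 4L * (gidx[, p] - 1L) + tidx[, p]
    X[cbind(seq_len(n), col)] <- 1
  }
  mm <- tmat != gmat
  if (flavor == "full") {
    X <- cbind(X, rowSums(mm[, 1:10, drop = FALSE]),
               rowSums(mm[, 11:20, drop = FALSE]))
  } else {
    X <- cbind(X, rowSums(mm[, 11:20, drop = FALSE]))
  }
  colnames(X) <- feature_names_flavor(flavor)
  X
}

#' @rdname encode_pairs
#' @export
encode_pair <- function(protospacer, guide, flavor = c("full", "reduced")) {
  stopifnot(length(protospacer) == 1L, length(guide) == 1L)
  encode_pairs(protospacer, guide, flavor)[1L, ]
}

#' Select training instances from a scission table
#'
#' Keeps sites with at least `min_proximal` raw proximal molecules, caps
#' the number of sites per guide at `per_guide_cap` to avoid promiscuous
#' guides dominating the set, and balances the blunt/staggered class mix
#' per guide: with `K` the ratio of staggered (blunt fraction < 0.2) to
#' blunt (blunt fraction > 0.8) sites, the majority class is subsampled
#' toward parity (staggered kept with probability `1/K` when `K > 1`,
#' blunt kept with probability `K` when `K < 1`).
#'
#' @param scission_table output of [scission_profile()] with a `guide`
#'   column.
#' @param min_proximal minimum proximal molecules.
#' @param per_guide_cap maximum sites per guide.
#' @param seed RNG seed for the subsampling.
#' @return filtered instance tibble.
#' @export
select_training_instances <- function(scission_table, min_proximal = 16L,
                                      per_guide_cap = 100L, seed = 1L) {
  if (nrow(scission_table) == 0L) stop("empty scission table", call. = FALSE)
  d <- filter(scission_table, .data$computable,
              .data$proximal_total >= min_proximal)
  withr::with_seed(seed, {
    d |>
      group_by(.data$guide) |>
      dplyr::group_modify(function(g, key) {
        n_stag <- sum(g$blunt_fraction < 0.2)
        n_blunt <- sum(g$blunt_fraction > 0.8)
        keep_p <- rep(1, nrow(g))
        if (n_stag > 0 && n_blunt > 0) {
          K <- n_stag / n_blunt
          if (K > 1) keep_p[g$blunt_fraction < 0.2] <- 1 / K
          if (K < 1) keep_p[g$blunt_fraction > 0.8] <- K
        }
        g <- g[runif(nrow(g)) <= keep_p, ]
        if (nrow(g) > per_guide_cap) {
          g <- g[sample.int(nrow(g), per_guide_cap), ]
        }
        g
      }) |>
      ungroup()
  })
}

default_xgb_params <- function(seed, extra = list()) {
  base <- list(booster = "dart", max_depth = 0L, grow_policy = "lossguide",
               tree_method = "hist", eta = 0.3, nthread = 1L,
               seed = seed, rate_drop = 0, skip_drop = 0)
  utils::modifyList(base, extra)
}

#' Train a gradient-boosted blunt-rate model
#'
#' Fits a DART-boosted tree ensemble (trees of unlimited depth) regressing
#' the log2 blunt rate -- `log2((c17 + 1) / (c[14-16,18-20] + 1))` -- on
#' the one-hot protospacer/guide encoding of [encode_pairs()]. K-fold
#' cross-validation produces out-of-fold predictions whose Pearson
#' correlation with the observed response is reported; the returned model
#' is refit on all instances.
#'
#' @param instances tibble with `protospacer`, `spacer` (guide sequence)
#'   and `response` (log2 blunt rate) columns; [instances_from_profiles()]
#'   builds it from a scission table.
#' @param flavor encoding flavor, `"full"` (322 variables) or `"reduced"`
#'   (161 variables, positions 11-20).
#' @param seed RNG seed (fold assignment and boosting).
#' @param nrounds number of boosting rounds (trees).
#' @param nfolds cross-validation folds.
#' @param params named list overriding the xgboost parameters.
#' @param min_instances minimum training-set size.
#' @return object of class `blunt_model` with the fitted booster, CV
#'   predictions (`cv`), held-out Pearson `cv_r`, and metadata. Supports
#'   [predict.blunt_model()], [tidy.blunt_model()], [glance.blunt_model()]
#'   and [save_blunt_model()].
#' @export
train_blunt_model <- function(instances, flavor = c("full", "reduced"),
                              seed = 1L, nrounds = 1000L, nfolds = 5L,
                              params = list(), min_instances = 100L) {
  flavor <- match.arg(flavor)
  stopifnot(all(c("protospacer", "spacer", "response") %in% names(instances)))
  if (nrow(instances) < min_instances) {
    stop("need at least ", min_instances, " training instances", call. = FALSE)
  }
  y <- instances$response
  if (stats::sd(y) == 0) stop("degenerate constant response", call. = FALSE)
  X <- encode_pairs(instances$protospacer, instances$spacer, flavor)
  pars <- default_xgb_params(seed, params)
  n <- nrow(X)
  withr::with_seed(seed, {
    fold <- sample(rep_len(seq_len(nfolds), n))
    cv_pred <- numeric(n)
    for (f in seq_len(nfolds)) {
      tr <- fold != f
      bst <- xgboost::xgb.train(
        params = pars,
        data = xgboost::xgb.DMatrix(X[tr, , drop = FALSE], label = y[tr]),
        nrounds = nrounds, verbose = 0)
      cv_pred[!tr] <- predict(bst, xgboost::xgb.DMatrix(X[!tr, , drop = FALSE]))
    }
    booster <- xgboost::xgb.train(
      params = pars, data = xgboost::xgb.DMatrix(X, label = y),
      nrounds = nrounds, verbose = 0)
  })
  structure(list(booster = booster, flavor = flavor,
                 feature_names = colnames(X),
                 nrounds = nrounds, nfolds = nfolds, params = pars,
                 seed = seed, n_instances = n,
                 cv = tibble(fold = fold, observed = y, predicted = cv_pred),
                 cv_r = cor(cv_pred, y)),
            class = "blunt_model")
}

#' Build model instances from scission profiles
#'
#' Joins guide spacers onto a (selected) scission table and exposes the
#' pseudocounted log2 blunt rate as the model response.
#'
#' @param profiles scission table (after [select_training_instances()]).
#' @param guides tibble of guides (`name`, `spacer`).
#' @return instance tibble for [train_blunt_model()].
#' @export
instances_from_profiles <- function(profiles, guides) {
  profiles |>
    left_join(select(guides, guide = "name", "spacer"), by = "guide") |>
    mutate(response = .data$log2_blunt_rate) |>
    select("guide", "protospacer", "spacer", "response",
           dplyr::starts_with("prox_"), "proximal_total")
}

#' @export
print.blunt_model <- function(x, ...) {
  cat(sprintf("Blunt-rate model (%s flavor): %d variables, %d trees, %d instances\n",
              x$flavor, length(x$feature_names), x$nrounds, x$n_instances))
  cat(sprintf("%d-fold CV Pearson r = %.3f\n", x$nfolds, x$cv_r))
  invisible(x)
}

#' Predict log2 blunt rates for protospacer/guide pairs
#'
#' @param object a `blunt_model`.
#' @param newdata tibble with `protospacer` and `spacer` columns (or a
#'   pre-encoded matrix with matching columns).
#' @param ... unused.
#' @return numeric vector of predicted log2 blunt rates, in input order.
#' @export
predict.blunt_model <- function(object, newdata, ...) {
  X <- if (is.matrix(newdata)) {
    if (!identical(colnames(newdata), object$feature_names)) {
      stop("encoded matrix does not match the model's ", object$flavor,
           " flavor", call. = FALSE)
    }
    newdata
  } else {
    guide <- if ("spacer" %in% names(newdata)) newdata$spacer
             else newdata$protospacer
    encode_pairs(newdata$protospacer, guide, object$flavor)
  }
  predict(object$booster, xgboost::xgb.DMatrix(X))
}

#' Per-variable importance of a blunt-rate model
#'
#' Ensemble gain importance per encoded variable, scaled so the most
#' important variable is 1. With `aggregate = TRUE`, indicator cells are
#' summed per (position, protospacer base) before scaling, which is the
#' natural resolution for 0-mismatch (guide = protospacer) applications.
#'
#' @param model a `blunt_model`.
#' @param aggregate sum the 4 guide-base cells per (position, protospacer
#'   base)?
#' @return tibble with `feature` (or `position` + `base`), `gain` and
#'   `importance` (scaled to max 1).
#' @export
feature_importance <- function(model, aggregate = TRUE) {
  imp <- xgboost::xgb.importance(model = model$booster)
  full <- tibble(feature = model$feature_names) |>
    left_join(tibble(feature = imp$Feature, gain = imp$Gain), by = "feature") |>
    mutate(gain = ifelse(is.na(.data$gain), 0, .data$gain))
  if (!aggregate) {
    return(mutate(full, importance = .data$gain / max(.data$gain)) |>
             arrange(desc(.data$importance)))
  }
  cells <- filter(full, grepl("^p[0-9]{2}_t", .data$feature)) |>
    mutate(position = as.integer(substr(.data$feature, 2, 3)),
           base = substr(.data$feature, 6, 6)) |>
    group_by(.data$position, .data$base) |>
    summarise(gain = sum(.data$gain), .groups = "drop")
  mutate(cells, importance = .data$gain / max(.data$gain)) |>
    arrange(desc(.data$importance))
}

#' @rdname feature_importance
#' @param x a `blunt_model`.
#' @param ... unused.
#' @export
tidy.blunt_model <- function(x, ...) feature_importance(x, aggregate = FALSE)

#' One-row summary of a blunt-rate model
#' @param x a `blunt_model`.
#' @param ... unused.
#' @export
glance.blunt_model <- function(x, ...) {
  tibble(flavor = x$flavor, n_instances = x$n_instances,
         n_variables = length(x$feature_names), nrounds = x$nrounds,
         nfolds = x$nfolds, cv_r = x$cv_r)
}

#' Save or load a blunt-rate model as portable JSON
#'
#' The booster is serialised in xgboost's JSON format and embedded with
#' the model metadata in a single JSON file; loading reproduces identical
#' predictions.
#'
#' @param model a `blunt_model`.
#' @param path output path.
#' @return `load_blunt_model()` returns the restored `blunt_model`.
#' @export
save_blunt_model <- function(model, path) {
  payload <- list(
    flavor = model$flavor, feature_names = model$feature_names,
    nrounds = model$nrounds, nfolds = model$nfolds, seed = model$seed,
    n_instances = model$n_instances, cv_r = model$cv_r,
    params = model$params[setdiff(names(model$params), "nthread")],
    booster_json = rawToChar(xgboost::xgb.save.raw(model$booster,
                                                   raw_format = "json")))
  write_atomic(function(tmp) {
    jsonlite::write_json(payload, tmp, auto_unbox = TRUE, digits = NA)
  }, path)
}

#' @rdname save_blunt_model
#' @export
load_blunt_model <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  booster <- xgboost::xgb.load.raw(charToRaw(payload$booster_json))
  structure(list(booster = booster, flavor = payload$flavor,
                 feature_names = payload$feature_names,
                 nrounds = payload$nrounds, nfolds = payload$nfolds,
                 params = payload$params, seed = payload$seed,
                 n_instances = payload$n_instances,
                 cv = NULL, cv_r = payload$cv_r),
            class = "blunt_model")
}

#' Independent per-position nucleotide effects on the blunt rate
#'
#' For each protospacer position, fits an ordinary least-squares
#' regression of the observed log2 blunt rate on the base identity under a
#' sum-to-zero contrast, so the four coefficients at a position sum to
#' zero. Positions at which fewer than two bases are observed are flagged
#' with NA coefficients.
#'
#' @param scission_table tibble with `protospacer` and `log2_blunt_rate`
#'   (or `response`) columns; at least 50 rows.
#' @return tibble with `position`, `base`, `estimate` and `n_obs`.
#' @export
per_position_effect <- function(scission_table) {
  y <- scission_table[["response"]] %||% scission_table[["log2_blunt_rate"]]
  if (length(y) < 50L) stop("need at least 50 sites", call. = FALSE)
  tmat <- do.call(rbind, strsplit(scission_table$protospacer, ""))
  purrr::map_dfr(1:20, function(p) {
    base <- factor(tmat[, p], levels = BASES)
    present <- levels(droplevels(base))
    if (length(present) < 2L) {
      return(tibble(position = p, base = BASES, estimate = NA_real_,
                    n_obs = as.integer(table(base))))
    }
    b <- droplevels(base)
    fit <- lm(y ~ C(b, stats::contr.sum))
    eff <- coef(fit)[-1]
    est <- setNames(rep(NA_real_, 4), BASES)
    est[present] <- c(eff, -sum(eff))
    tibble(position = p, base = BASES, estimate = unname(est),
           n_obs = as.integer(table(base)))
  })
}

#' Mean predicted blunt rate for all position-17/18 base combinations
#'
#' Substitutes each of the 16 (base 17, base 18) combinations into every
#' background protospacer (guide matched, 0 mismatches), predicts with the
#' model and averages, yielding the 4x4 combination grid.
#'
#' @param model a `blunt_model`.
#' @param background_sequences character vector of 20-nt protospacers
#'   (at least 100 recommended).
#' @return tibble with `base17`, `base18` and `mean_predicted_rate`.
#' @export
combo_grid_17_18 <- function(model, background_sequences) {
  assert_spacer(background_sequences, "background sequence")
  grid <- tidyr::crossing(base17 = BASES, base18 = BASES)
  grid$mean_predicted_rate <- purrr::map2_dbl(
    grid$base17, grid$base18, function(b17, b18) {
      s <- background_sequences
      substr(s, 17, 17) <- b17
      substr(s, 18, 18) <- b18
      mean(predict(model, tibble(protospacer = s, spacer = s)))
    })
  grid
}
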