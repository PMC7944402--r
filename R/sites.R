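#' Mutant configuration for the additive binding-site model
#'
#' Encodes which binding-site-relevant mutations a Shaker Kv construct
#' carries: the 2R motif (M356R/A359R, two extra arginines at the top of
#' S4), neutralisation of the outer gating charges R362 and/or R365, and
#' the aromatic pocket mutations W454A (top of S6) and F416A (top of S5).
#'
#' @param label Unique construct label (e.g. `"2R/R362Q"`).
#' @param has_2R 2R motif present?
#' @param R362Q,R365Q,W454A,F416A Point-mutation flags.
#' @return An object of class `"mutant_config"`.
#' @export
mutant_config <- function(label, has_2R = FALSE, R362Q = FALSE,
                          R365Q = FALSE, W454A = FALSE, F416A = FALSE) {
  structure(list(label = as.character(label),
                 has_2R = isTRUE(has_2R), R362Q = isTRUE(R362Q),
                 R365Q = isTRUE(R365Q), W454A = isTRUE(W454A),
                 F416A = isTRUE(F416A)),
            class = "mutant_config")
}

# The four S4/pore configuration classes of the published constraint set.
# Mutants carrying R365Q or F416A fall outside them and are represented by
# extended classes so that the class registry can grow with the data.
.canonical_pore_classes <- c("WT_362_454", "R362Q", "W454A", "R362Q_W454A")
.known_extended_classes <- c("R362Q_R365Q", "R362Q_R365Q_W454A")

#' Encode a mutant into the additive-model terms
#'
#' Maps a [mutant_config()] onto the three terms of the additive shift
#' model: the S3/S4-site term is active only when the 2R motif is present
#' (without the two added arginines the compound does not stay bound
#' there, so that contribution is pinned at zero); the S4/pore term takes
#' one value per pore configuration class — `WT_362_454`, `R362Q`,
#' `W454A`, `R362Q_W454A` for the four canonical classes, with
#' R365Q/F416A-containing mutants mapped to extended classes; and the
#' residual term (all remaining sites, notably the top-VSD pocket) is
#' active for every mutant.
#'
#' @param config A [mutant_config()].
#' @return List with `s3s4_active`, `pore_class` and `residual_active`.
#' @examples
#' encode_mutant(mutant_config("WT"))
#' encode_mutant(mutant_config("2R/W454A", has_2R = TRUE, W454A = TRUE))
#' @export
encode_mutant <- function(config) {
  stopifnot(inherits(config, "mutant_config"))
  if (!config$R365Q && !config$F416A) {
    pore <- if (config$R362Q && config$W454A) "R362Q_W454A"
            else if (config$R362Q) "R362Q"
            else if (config$W454A) "W454A"
            else "WT_362_454"
  } else {
    flags <- c("R362Q", "R365Q", "W454A", "F416A")
    pore <- paste(flags[vapply(flags, function(f) isTRUE(config[[f]]),
                               logical(1))], collapse = "_")
    if (!pore %in% .known_extended_classes)
      warning("mutant '", config$label, "': pore configuration '", pore,
              "' is outside the canonical and known extended classes; ",
              "treating it as its own class")
  }
  list(s3s4_active = config$has_2R, pore_class = pore, residual_active = TRUE)
}

# Turn the flag columns of a shift dataset into mutant_config objects.
dataset_configs <- function(dataset) {
  need <- c("mutant_label", "has_2R", "R362Q", "R365Q", "W454A", "F416A")
  miss <- setdiff(need, names(dataset))
  if (length(miss))
    stop("shift dataset is missing column(s): ", paste(miss, collapse = ", "))
  lapply(seq_len(nrow(dataset)), function(i)
    mutant_config(dataset$mutant_label[i],
                  has_2R = dataset$has_2R[i], R362Q = dataset$R362Q[i],
                  R365Q = dataset$R365Q[i], W454A = dataset$W454A[i],
                  F416A = dataset$F416A[i]))
}

#' Build the indicator design matrix of the additive site model
#'
#' One row per mutant, one column per model term: an S3/S4 indicator
#' (active with the 2R motif), one indicator per S4/pore configuration
#' class present in the dataset, and an all-ones residual column. Each row
#' sums exactly the terms that are active for that mutant, so the model
#' prediction is `X %*% beta`.
#'
#' @param dataset Shift dataset: data frame with columns `mutant_label`,
#'   `has_2R`, `R362Q`, `R365Q`, `W454A`, `F416A` (and typically
#'   `shift_mV`).
#' @param zero_pore_when_2R If `TRUE`, the S4/pore indicator is zeroed for
#'   mutants carrying the 2R motif — the model variant in which the S3/S4
#'   site dominates and the pore pocket adds nothing once the 2R motif is
#'   present.
#' @return List with `X` (rows x parameters indicator matrix), `labels`
#'   (parameter names), `pore_classes` (classes in column order) and
#'   `rank` (numerical rank of `X`; rank < ncol flags a degenerate
#'   design).
#' @export
build_design_matrix <- function(dataset, zero_pore_when_2R = FALSE) {
  if (nrow(dataset) == 0) stop("empty shift dataset")
  enc <- lapply(dataset_configs(dataset), encode_mutant)
  classes_seen <- unique(vapply(enc, `[[`, character(1), "pore_class"))
  classes <- c(intersect(.canonical_pore_classes, classes_seen),
               setdiff(classes_seen, .canonical_pore_classes))
  labels <- c("s3s4", paste0("pore_", classes), "residual")
  X <- matrix(0, nrow = nrow(dataset), ncol = length(labels),
              dimnames = list(dataset$mutant_label, labels))
  for (i in seq_along(enc)) {
    if (enc[[i]]$s3s4_active) X[i, "s3s4"] <- 1
    pore_on <- !(zero_pore_when_2R && enc[[i]]$s3s4_active)
    if (pore_on) X[i, paste0("pore_", enc[[i]]$pore_class)] <- 1
    X[i, "residual"] <- 1
  }
  list(X = X, labels = labels, pore_classes = classes, rank = qr(X)$rank)
}

# Minimum-norm least squares via SVD; returns solution plus the pieces
# solution_ranges() needs (singular vectors/values and numerical rank).
minnorm_ls <- function(X, y, tol = 1e-10) {
  sv <- svd(X)
  keep <- sv$d > tol * max(sv$d, 0)
  r <- sum(keep)
  beta <- if (r == 0) rep(0, ncol(X)) else
    sv$v[, keep, drop = FALSE] %*%
      ((t(sv$u[, keep, drop = FALSE]) %*% y) / sv$d[keep])
  list(beta = drop(beta), v = sv$v[, keep, drop = FALSE], d = sv$d[keep],
       rank = r)
}

#' Fit the additive binding-site model to a mutant shift panel
#'
#' Least-squares estimate of the per-site shift contributions
#' (S3/S4 term, one S4/pore term per configuration class, residual) from a
#' panel of per-mutant G(V) shifts, all measured at one compound
#' concentration. Parameters may be pinned with `fixed` (the published
#' analysis pins the residual, which breaks the intrinsic
#' residual-vs-pore degeneracy of panels in which every mutant carries a
#' pore term). When the free design is rank-deficient the minimum-norm
#' solution is returned and the real uncertainty should be read from
#' [solution_ranges()].
#'
#' @inheritParams build_design_matrix
#' @param fixed Optional named numeric vector pinning parameters (names
#'   from the design labels, e.g. `c(residual = -10)`).
#' @param weights Optional per-row weights (e.g. `1/sem^2`); default
#'   unweighted.
#' @return Object of class `"site_model_fit"`: `coefficients` (all
#'   parameters, fixed ones at their pinned values), `fixed`, `sse`
#'   (of the weighted objective if weights are given), `rank`,
#'   `n_parameters`, `degenerate` flag, `predicted` (named per-mutant
#'   model shifts), `pearson_r` (predicted vs observed), and internal
#'   fitting state used by [solution_ranges()].
#' @examples
#' ds <- load_published_shifts("Wu50")
#' fit_site_model(ds[ds$model_panel, ], fixed = c(residual = -10))
#' @export
fit_site_model <- function(dataset, fixed = NULL, weights = NULL,
                           zero_pore_when_2R = FALSE) {
  if (!"shift_mV" %in% names(dataset)) stop("dataset lacks a 'shift_mV' column")
  drop <- !is.finite(dataset$shift_mV)
  if (any(drop)) {
    warning("dropping ", sum(drop), " row(s) without a numeric shift")
    dataset <- dataset[!drop, , drop = FALSE]
    if (!is.null(weights)) weights <- weights[!drop]
  }
  dm <- build_design_matrix(dataset, zero_pore_when_2R = zero_pore_when_2R)
  X <- dm$X
  y <- dataset$shift_mV
  if (!is.null(fixed)) {
    bad <- setdiff(names(fixed), dm$labels)
    if (length(bad))
      stop("fixed parameter(s) not in the design: ", paste(bad, collapse = ", "))
  }
  free <- setdiff(dm$labels, names(fixed))
  y_adj <- if (is.null(fixed) || length(fixed) == 0) y else
    y - X[, names(fixed), drop = FALSE] %*% fixed
  sw <- if (is.null(weights)) rep(1, nrow(X)) else sqrt(weights)
  Xw <- X[, free, drop = FALSE] * sw
  yw <- drop(y_adj) * sw
  if (length(free) > 0) {
    sol <- minnorm_ls(Xw, yw)
    beta_free <- setNames(sol$beta, free)
  } else {
    sol <- list(v = matrix(0, 0, 0), d = numeric(0), rank = 0)
    beta_free <- setNames(numeric(0), character(0))
  }
  coefs <- setNames(numeric(length(dm$labels)), dm$labels)
  coefs[free] <- beta_free
  if (!is.null(fixed)) coefs[names(fixed)] <- fixed
  predicted <- drop(X %*% coefs)
  names(predicted) <- dataset$mutant_label
  resid <- y - predicted
  sse <- sum((sw * resid)^2)
  pr <- if (length(predicted) < 2 ||
            sd(predicted) < .Machine$double.eps^0.5) NA_real_ else
    cor(predicted, y)
  out <- list(coefficients = coefs, fixed = fixed, sse = sse,
              rank = if (length(free)) sol$rank else 0L,
              n_parameters = length(dm$labels),
              degenerate = length(free) > 0 && sol$rank < length(free),
              predicted = predicted, observed = setNames(y, dataset$mutant_label),
              pearson_r = pr, pore_classes = dm$pore_classes,
              free = free, design = X,
              .svd = sol, .Xw = Xw, .yw = yw)
  class(out) <- "site_model_fit"
  out
}

#' @export
print.site_model_fit <- function(x, ...) {
  cat("Additive binding-site model fit\n")
  cat("  parameters (mV):\n")
  for (nm in names(x$coefficients))
    cat(sprintf("    %-22s %8.2f%s\n", nm, x$coefficients[nm],
                if (nm %in% names(x$fixed)) "  [fixed]" else ""))
  cat(sprintf("  sse = %.3f mV^2 over %d mutants; rank %d/%d free parameters%s\n",
              x$sse, length(x$predicted), x$rank, length(x$free),
              if (x$degenerate) " (DEGENERATE: see solution_ranges())" else ""))
  if (is.finite(x$pearson_r))
    cat(sprintf("  Pearson r (predicted vs observed) = %.3f\n", x$pearson_r))
  invisible(x)
}

#' Solution ranges of the site-model parameters
#'
#' For each free parameter, the interval of values attainable by *any*
#' parameter vector whose (weighted) sum of squared errors stays within a
#' tolerance of the minimum. The interval is closed-form: along the
#' row space of the design the sse sublevel set is an ellipsoid, so the
#' range of a coordinate is `estimate +/- sqrt(slack * e' (X'X)^+ e)`;
#' a parameter with a component in the null space of the design (a flat
#' ridge, e.g. the residual-vs-pore trade-off when every mutant carries a
#' pore term) is unbounded and flagged as such with a warning.
#'
#' @param fit A [fit_site_model()] result.
#' @param tolerance Allowed sse excess. Interpreted as a fraction of the
#'   minimum sse by default (0.05 = within 5% of the best fit), or as an
#'   absolute mV^2 value when `absolute = TRUE`.
#' @param absolute Is `tolerance` an absolute sse excess (mV^2)?
#' @return Data frame with columns `parameter`, `low`, `high`,
#'   `unbounded`, `fixed`. Fixed parameters have zero-width intervals at
#'   their pinned value.
#' @export
solution_ranges <- function(fit, tolerance = 0.05, absolute = FALSE) {
  stopifnot(inherits(fit, "site_model_fit"), tolerance >= 0)
  slack <- if (absolute) tolerance else tolerance * fit$sse
  sv <- fit$.svd
  params <- names(fit$coefficients)
  low <- high <- setNames(rep(NA_real_, length(params)), params)
  unbounded <- setNames(rep(FALSE, length(params)), params)
  for (nm in params) {
    if (nm %in% names(fit$fixed)) {
      low[nm] <- high[nm] <- fit$fixed[[nm]]
      next
    }
    j <- match(nm, fit$free)
    e <- rep(0, length(fit$free)); e[j] <- 1
    proj <- if (sv$rank > 0) drop(t(sv$v) %*% e) else numeric(0)
    null_part <- sum(e^2) - sum(proj^2)
    if (null_part > 1e-8) {
      unbounded[nm] <- TRUE
      low[nm] <- -Inf; high[nm] <- Inf
    } else {
      half <- sqrt(max(slack, 0) * sum((proj / sv$d)^2))
      low[nm] <- fit$coefficients[nm] - half
      high[nm] <- fit$coefficients[nm] + half
    }
  }
  if (any(unbounded))
    warning("parameter(s) ", paste(params[unbounded], collapse = ", "),
            " lie on a flat ridge of the design and are unbounded; ",
            "pin one of them (e.g. the residual) to resolve the degeneracy")
  data.frame(parameter = params, low = unname(low), high = unname(high),
             unbounded = unname(unbounded),
             fixed = params %in% names(fit$fixed), row.names = NULL)
}

#' Model-predicted shifts and their correlation with observation
#'
#' Applies a fitted additive site model to a shift panel (by default the
#' one it was fitted to) and reports the per-mutant predicted shifts
#' together with the Pearson correlation between predicted and observed
#' values — the model-adequacy summary used for this decomposition.
#'
#' @param fit A [fit_site_model()] result.
#' @param dataset Optional new shift dataset; every pore class occurring in
#'   it must be covered by the fitted parameters.
#' @return List with `predicted` (named mV vector), `observed` and
#'   `pearson_r` (`NA` with a message if the predictions are constant).
#' @export
predict_and_correlate <- function(fit, dataset = NULL) {
  stopifnot(inherits(fit, "site_model_fit"))
  if (is.null(dataset)) {
    predicted <- fit$predicted
    observed <- fit$observed
  } else {
    keep <- is.finite(dataset$shift_mV)
    dataset <- dataset[keep, , drop = FALSE]
    dm <- build_design_matrix(dataset)
    missing_par <- setdiff(dm$labels, names(fit$coefficients))
    if (length(missing_par))
      stop("fit does not cover parameter(s) required by the dataset: ",
           paste(missing_par, collapse = ", "))
    predicted <- drop(dm$X %*% fit$coefficients[dm$labels])
    names(predicted) <- dataset$mutant_label
    observed <- setNames(dataset$shift_mV, dataset$mutant_label)
  }
  r <- if (length(predicted) < 2 ||
           sd(predicted) < .Machine$double.eps^0.5) {
    message("constant model predictions: Pearson r is undefined")
    NA_real_
  } else cor(predicted, observed)
  list(predicted = predicted, observed = observed, pearson_r = r)
}
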