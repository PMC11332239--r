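#' Residual ornament size from an allometric regression
#'
#' Size-corrected ornament length: the residuals of an ordinary
#' least-squares regression of ornament length against body mass across the
#' panel. By default both variables are log-transformed (the standard
#' allometric power-law form); `log = FALSE` fits on the raw scales for
#' sensitivity analysis. Rows with non-positive length or mass are excluded
#' from the fit (with a message) and receive `NA` residuals.
#'
#' @param length Ornament length (mm), e.g. beak or tail.
#' @param body_mass Body mass (g).
#' @param log Fit on log-log scales? Default `TRUE`.
#' @return Numeric residual vector aligned with the input (sums to ~0 over
#'   the used rows).
#' @examples
#' m <- c(10, 100, 1000)
#' relative_ornament(2 * m^(1 / 3), m)  # exact power law -> residuals 0
#' @export
relative_ornament <- function(length, body_mass, log = TRUE) {
  abort_if(base::length(length) != base::length(body_mass),
           "length and body_mass must have equal length")
  ok <- is.finite(length) & is.finite(body_mass)
  if (log) ok <- ok & length > 0 & body_mass > 0
  n_bad <- sum(!ok)
  if (n_bad > 0) {
    message(sprintf("relative_ornament: %d row(s) with non-positive or missing values excluded", n_bad))
  }
  abort_if(sum(ok) < 3, "need at least 3 usable species for the allometric fit")
  y <- if (log) base::log(length[ok]) else length[ok]
  x <- if (log) base::log(body_mass[ok]) else body_mass[ok]
  fit <- stats::lm.fit(cbind(1, x), y)
  out <- rep(NA_real_, base::length(length))
  out[ok] <- fit$residuals
  out
}

IUCN_MAP <- c(
  "Least Concern" = "Non-threatened", "Near Threatened" = "Non-threatened",
  "Vulnerable" = "Threatened", "Endangered" = "Threatened",
  "Critically Endangered" = "Threatened",
  "Data Deficient" = "Unknown", "Not Evaluated" = "Unknown"
)
TROPHIC_MAP <- c(
  "Carnivore" = "carnivore", "Predator" = "carnivore",
  "Scavenger" = "carnivore", "Invertivore" = "carnivore",
  "Omnivore" = "omnivore",
  "Herbivore" = "herbivore", "Frugivore" = "herbivore",
  "Granivore" = "herbivore", "Nectarivore" = "herbivore"
)
MIGRATION_MAP <- c(
  "Full migrant" = "migratory", "Partial migrant" = "migratory",
  "Migrant" = "migratory",
  "Resident" = "non-migratory", "Sedentary" = "non-migratory"
)

reclassify_with <- function(x, map, what) {
  unknown <- setdiff(unique(x), names(map))
  abort_if(length(unknown) > 0,
           sprintf("unknown %s label(s): %s", what,
                   paste(unknown, collapse = ", ")))
  unname(map[x])
}

#' Collapse raw categorical labels into balanced analysis categories
#'
#' Deterministic reclassifications: IUCN Red List categories collapse to
#' Threatened (Vulnerable, Endangered, Critically Endangered),
#' Non-threatened (Least Concern, Near Threatened) and Unknown (Data
#' Deficient, Not Evaluated); trophic labels collapse to carnivore (all
#' predators, scavengers and invertivores), omnivore and herbivore;
#' migration labels collapse to migratory (partial or full migrant) versus
#' non-migratory (resident). Unknown raw labels raise an error naming the
#' label.
#'
#' @param x Character vector of raw labels.
#' @return Character vector of collapsed categories.
#' @examples
#' reclassify_iucn("Critically Endangered")  # "Threatened"
#' reclassify_trophic("Invertivore")         # "carnivore"
#' reclassify_migration("Partial migrant")   # "migratory"
#' @export
reclassify_iucn <- function(x) reclassify_with(x, IUCN_MAP, "IUCN")

#' @rdname reclassify_iucn
#' @export
reclassify_trophic <- function(x) reclassify_with(x, TROPHIC_MAP, "trophic")

#' @rdname reclassify_iucn
#' @export
reclassify_migration <- function(x) reclassify_with(x, MIGRATION_MAP, "migration")

#' Log-transform, absolute-value and z-scale predictor columns
#'
#' Applies, in order: natural log to `log_vars` (body mass and range size by
#' convention), absolute value to `abs_vars` (range-centroid latitude), then
#' centring/scaling to mean 0 and SD 1 for all `scale_vars`. The scaling
#' constants are stored so the transform is invertible.
#'
#' @param data A data frame / tibble.
#' @param log_vars,abs_vars,scale_vars Character vectors of column names;
#'   `scale_vars` defaults to `union(log_vars, abs_vars)`. A zero-variance
#'   scaled column is an error naming the column.
#' @return `data` with transformed columns and an attribute `scaling`
#'   (tibble: `var`, `mean`, `sd`, `logged`, `absed`).
#' @seealso [inverse_transform()]
#' @export
transform_and_scale <- function(data, log_vars = c("body_mass", "range_size"),
                                abs_vars = character(),
                                scale_vars = NULL) {
  if (is.null(scale_vars)) scale_vars <- union(log_vars, abs_vars)
  all_vars <- unique(c(log_vars, abs_vars, scale_vars))
  missing <- setdiff(all_vars, names(data))
  abort_if(length(missing) > 0,
           paste("columns not found:", paste(missing, collapse = ", ")))
  for (v in log_vars) {
    abort_if(any(data[[v]] <= 0, na.rm = TRUE),
             sprintf("column '%s' has non-positive values; cannot log", v))
    data[[v]] <- log(data[[v]])
  }
  for (v in abs_vars) data[[v]] <- abs(data[[v]])
  sc <- tibble::tibble(var = scale_vars, mean = NA_real_, sd = NA_real_,
                       logged = scale_vars %in% log_vars,
                       absed = scale_vars %in% abs_vars)
  for (i in seq_along(scale_vars)) {
    v <- scale_vars[i]
    m <- mean(data[[v]], na.rm = TRUE)
    s <- stats::sd(data[[v]], na.rm = TRUE)
    abort_if(!is.finite(s) || s == 0,
             sprintf("column '%s' has zero variance; cannot scale", v))
    sc$mean[i] <- m; sc$sd[i] <- s
    data[[v]] <- (data[[v]] - m) / s
  }
  attr(data, "scaling") <- sc
  data
}

#' Invert [transform_and_scale()]
#'
#' @param data A table produced by [transform_and_scale()] (or any table
#'   with the same columns).
#' @param scaling The `scaling` attribute of the forward transform; taken
#'   from `data` if absent.
#' @return `data` with the original column values restored (absolute value
#'   is not invertible and is left as-is).
#' @export
inverse_transform <- function(data, scaling = NULL) {
  scaling <- scaling %||% attr(data, "scaling")
  abort_if(is.null(scaling), "no scaling information available")
  for (i in seq_len(nrow(scaling))) {
    v <- scaling$var[i]
    data[[v]] <- data[[v]] * scaling$sd[i] + scaling$mean[i]
    if (scaling$logged[i]) data[[v]] <- exp(data[[v]])
  }
  attr(data, "scaling") <- NULL
  data
}

#' Pairwise collinearity screen for continuous predictors
#'
#' Reports all pairwise Pearson correlations among the given predictor
#' columns and flags pairs whose |r| exceeds the threshold. Nothing is
#' dropped automatically: the caller supplies an explicit, documented drop
#' list (conventionally colour diversity, which correlates strongly with
#' several colour proportions).
#'
#' @param data A data frame.
#' @param vars Character vector of continuous predictor columns; default:
#'   all numeric columns.
#' @param threshold Absolute correlation threshold, default 0.6.
#' @param drop Character vector of predictors to exclude from the retained
#'   set (documented drop list).
#' @return A list of class `collinearity_screen`: `report` (tibble `var1`,
#'   `var2`, `r`, `flagged`), `flagged` (the offending pairs), `retained`
#'   (vars minus `drop`), `threshold`, `max_abs_r_retained`.
#' @export
collinearity_screen <- function(data, vars = NULL, threshold = 0.6,
                                drop = character()) {
  if (is.null(vars)) {
    vars <- names(data)[vapply(data, is.numeric, logical(1))]
  }
  abort_if(length(vars) < 2, "need at least two continuous predictors")
  cm <- stats::cor(as.data.frame(data)[vars], use = "pairwise.complete.obs",
                   method = "pearson")
  idx <- which(upper.tri(cm), arr.ind = TRUE)
  report <- tibble::tibble(
    var1 = vars[idx[, 1]], var2 = vars[idx[, 2]],
    r = cm[idx]
  )
  report$flagged <- abs(report$r) > threshold
  report <- dplyr::arrange(report, dplyr::desc(abs(.data$r)))
  retained <- setdiff(vars, drop)
  kept <- report$var1 %in% retained & report$var2 %in% retained
  structure(list(report = report,
                 flagged = report[report$flagged, ],
                 retained = retained,
                 threshold = threshold,
                 max_abs_r_retained = if (any(kept)) max(abs(report$r[kept])) else NA_real_),
            class = "collinearity_screen")
}

#' @export
print.collinearity_screen <- function(x, ...) {
  cat(sprintf("collinearity screen: %d pairs, %d flagged at |r| > %.2f\n",
              nrow(x$report), nrow(x$flagged), x$threshold))
  if (nrow(x$flagged) > 0) {
    for (i in seq_len(min(10, nrow(x$flagged)))) {
      cat(sprintf("  %s ~ %s: r = %.3f\n", x$flagged$var1[i],
                  x$flagged$var2[i], x$flagged$r[i]))
    }
  }
  cat(sprintf("retained %d predictors; max |r| among retained = %.3f\n",
              length(x$retained), x$max_abs_r_retained))
  invisible(x)
}
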