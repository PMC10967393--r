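#' Specify the differential-expression model
#'
#' The response is per-gene logTPM. Fixed effects are a combined
#' disease x inflammation factor (levels HC-noninf, UC-noninf, UC-inf,
#' CD-noninf, CD-inf) plus optional adjustment covariates; random intercepts
#' are drawn from {batch, patient}. Inference is a Wald test of one factor
#' level against the reference on the continuous part of the two-part model.
#'
#' @param group_var metadata column holding the contrast factor.
#' @param contrast_level,reference factor levels compared (level vs ref).
#' @param covariates optional adjustment covariate columns (fixed effects).
#' @param random random-intercept factors, subset of c("batch", "patient").
#' @return list of class \code{de_model_spec}.
#' @export
de_model_spec <- function(group_var = "group", contrast_level, reference,
                          covariates = character(0),
                          random = c("batch")) {
  stopifnot(is.character(group_var), length(contrast_level) == 1)
  structure(list(group_var = group_var, contrast_level = contrast_level,
                 reference = reference, covariates = covariates,
                 random = random),
            class = "de_model_spec")
}

de_fixed_formula <- function(spec, response = "y") {
  rhs <- paste(c(spec$group_var, spec$covariates), collapse = " + ")
  stats::as.formula(paste(response, "~", rhs))
}

de_prepare_group <- function(data, spec) {
  g <- data[[spec$group_var]]
  if (!is.factor(g)) g <- factor(g)
  if (!spec$reference %in% levels(g))
    stop("reference level absent: ", spec$reference)
  stats::relevel(g, ref = spec$reference)
}

de_extract_contrast <- function(est, se_mat, spec) {
  nm <- paste0(spec$group_var, spec$contrast_level)
  if (!nm %in% names(est)) stop("contrast coefficient not found: ", nm)
  se <- sqrt(diag(se_mat))[nm]
  z <- unname(est[nm] / se)
  list(estimate = unname(est[nm]), se = unname(se), z = z,
       p = 2 * pnorm(-abs(z)))
}

#' Fit the zero-inflated Gaussian model for one gene
#'
#' A two-part (hurdle) formulation, exactly equivalent to a zero-inflated
#' model for a continuous response with a point mass at zero: the zero
#' indicator is modeled by logistic regression on the fixed effects, and the
#' strictly positive observations by a Gaussian linear mixed model with the
#' requested random intercepts (REML via lme4; plain least squares when no
#' random factor is present). Fold-change inference is reported from the
#' continuous part; an optional combined two-part chi-square test is
#' returned alongside.
#'
#' @param data data.frame with the response column \code{y} (logTPM) and
#'   the design columns named in \code{spec}.
#' @param spec a \code{\link{de_model_spec}}.
#' @return list with \code{estimate} (log2 fold-change), \code{se},
#'   \code{z}, \code{p}, \code{p_combined}, \code{zero_frac},
#'   \code{model_used}, \code{converged}.
#' @export
fit_zig <- function(data, spec) {
  stopifnot(inherits(spec, "de_model_spec"), "y" %in% names(data))
  data[[spec$group_var]] <- de_prepare_group(data, spec)
  nz <- data$y != 0
  zero_frac <- mean(!nz)
  if (all(!nz)) stop("all observations are zero")

  tab <- table(data[[spec$group_var]][nz])
  if (sum(tab >= 3) < 2)
    stop("need >= 2 groups with >= 3 nonzero observations")

  ## zero part: logistic regression of P(y == 0) on the fixed effects
  zero_fit <- NULL
  if (any(!nz)) {
    zdat <- data; zdat$z <- as.numeric(!nz)
    zero_fit <- tryCatch(
      suppressWarnings(glm(de_fixed_formula(spec, "z"), binomial(), zdat)),
      error = function(e) NULL)
  }

  ## continuous part on the positive observations
  cont <- fit_gaussian_part(data[nz, , drop = FALSE], spec)
  wald <- de_extract_contrast(cont$coefficients, cont$vcov, spec)

  p_combined <- NA_real_
  if (!is.null(zero_fit)) {
    zc <- tryCatch({
      est <- coef(zero_fit); V <- vcov(zero_fit)
      de_extract_contrast(est, V, spec)
    }, error = function(e) NULL)
    if (!is.null(zc) && is.finite(zc$z))
      p_combined <- stats::pchisq(wald$z^2 + zc$z^2, df = 2,
                                  lower.tail = FALSE)
  }

  list(estimate = wald$estimate, se = wald$se, z = wald$z, p = wald$p,
       p_combined = p_combined, zero_frac = zero_frac,
       sigma = cont$sigma, model_used = "zig", converged = cont$converged)
}

# Gaussian (mixed) model for a subset of observations; shared by the
# continuous part of fit_zig and by the all-observations fallback.
fit_gaussian_part <- function(dat, spec) {
  random <- intersect(spec$random, names(dat))
  random <- random[vapply(random, function(r)
    length(unique(dat[[r]])) > 1, logical(1))]
  if (length(random) == 0) {
    fit <- lm(de_fixed_formula(spec), dat)
    return(list(coefficients = coef(fit), vcov = vcov(fit),
                sigma = summary(fit)$sigma, converged = TRUE))
  }
  re_terms <- paste(sprintf("(1 | %s)", random), collapse = " + ")
  fml <- stats::as.formula(paste(
    "y ~", paste(c(spec$group_var, spec$covariates), collapse = " + "),
    "+", re_terms))
  converged <- TRUE
  fit <- withCallingHandlers(
    tryCatch(
      lme4::lmer(fml, dat, REML = TRUE,
                 control = lme4::lmerControl(calc.derivs = FALSE,
                                             check.conv.singular = "ignore")),
      error = function(e) NULL),
    warning = function(w) {
      if (grepl("converge", conditionMessage(w), ignore.case = TRUE))
        converged <<- FALSE
      invokeRestart("muffleWarning")
    })
  if (is.null(fit))
    return(list(coefficients = NULL, vcov = NULL, sigma = NA, converged = FALSE))
  list(coefficients = lme4::fixef(fit),
       vcov = as.matrix(vcov(fit)),
       sigma = stats::sigma(fit), converged = converged)
}

#' Gaussian mixed-model fallback on all observations
#'
#' Applied when the zero-inflated fit does not converge: the same fixed and
#' random structure fit to all observations with zeros included.
#'
#' @inheritParams fit_zig
#' @return list as in \code{\link{fit_zig}} with
#'   \code{model_used = "lmm_fallback"}.
#' @export
fit_lmm_fallback <- function(data, spec) {
  data[[spec$group_var]] <- de_prepare_group(data, spec)
  cont <- fit_gaussian_part(data, spec)
  if (is.null(cont$coefficients)) stop("singular design in fallback model")
  wald <- de_extract_contrast(cont$coefficients, cont$vcov, spec)
  list(estimate = wald$estimate, se = wald$se, z = wald$z, p = wald$p,
       p_combined = NA_real_, zero_frac = mean(data$y == 0),
       sigma = cont$sigma, model_used = "lmm_fallback",
       converged = cont$converged)
}

#' Run differential expression across genes for one sampling location
#'
#' Subsets the cohort to the requested location (ileum, nonrectal colon, or
#' rectum), builds the combined disease x inflammation factor, fits the
#' zero-inflated Gaussian model per gene (falling back to the plain mixed
#' model on non-convergence), and adjusts p-values by Benjamini-Hochberg
#' within the location x contrast.
#'
#' Random effects default to the location-appropriate structure: batch for
#' ileum and rectum, patient + batch for nonrectal colon.
#'
#' @param expr \code{expr_matrix} on the logTPM scale with disease, tissue,
#'   inflamed, batch, patient metadata.
#' @param annotation gene annotation (for biotype in the result table).
#' @param contrast_level level of the combined factor tested vs "HC-noninf"
#'   (e.g. "UC-inf").
#' @param location one of "ileum", "colon_nonrectal", "rectum".
#' @param covariates optional adjustment covariates.
#' @param random random-intercept factors; NULL uses the location default.
#' @param concordance if TRUE and covariates are present, also fit the
#'   unadjusted model and report the concordance of significant calls.
#' @return data.frame (gene_id, biotype, lfc, se, p, p_adj, zero_frac,
#'   model_used, converged, excluded_reason). Concordance report, if any, in
#'   \code{attr(, "concordance")}.
#' @export
run_de <- function(expr, annotation, contrast_level,
                   location = c("ileum", "colon_nonrectal", "rectum"),
                   covariates = character(0), random = NULL,
                   concordance = FALSE) {
  stopifnot(inherits(expr, "expr_matrix"))
  location <- match.arg(location)
  tissue_sel <- switch(location, ileum = "ileum",
                       colon_nonrectal = "colon", rectum = "rectum")
  keep <- expr$samples$tissue == tissue_sel
  if (!any(keep)) stop("no samples for location: ", location)
  meta <- expr$samples[keep, , drop = FALSE]
  vals <- expr$values[keep, , drop = FALSE]

  meta$de_group <- interaction_group(meta)
  if (is.null(random))
    random <- if (location == "colon_nonrectal") c("patient", "batch")
              else "batch"
  spec <- de_model_spec("de_group", contrast_level, "HC-noninf",
                        covariates, random)
  fit_one <- function(g, sp) {
    dat <- cbind(data.frame(y = vals[, g]), meta)
    if (all(dat$y == 0))
      return(list(excluded = "all_zero"))
    res <- tryCatch(fit_zig(dat, sp), error = function(e)
      list(excluded = conditionMessage(e)))
    if (!is.null(res$excluded)) return(res)
    if (!res$converged) {
      fb <- tryCatch(fit_lmm_fallback(dat, sp), error = function(e) NULL)
      if (!is.null(fb)) res <- fb
    }
    res
  }
  genes <- colnames(vals)
  fits <- lapply(genes, fit_one, sp = spec)
  excluded <- vapply(fits, function(f) f$excluded %||% NA_character_, "")
  num <- function(fld) vapply(fits, function(f)
    if (is.null(f$excluded)) f[[fld]] else NA_real_, 0)
  chr <- function(fld) vapply(fits, function(f)
    if (is.null(f$excluded)) f[[fld]] else NA_character_, "")
  out <- data.frame(
    gene_id = genes,
    biotype = annotation$biotype[match(genes, annotation$gene_id)],
    lfc = num("estimate"), se = num("se"), p = num("p"),
    p_adj = NA_real_, zero_frac = num("zero_frac"),
    model_used = chr("model_used"),
    converged = vapply(fits, function(f)
      if (is.null(f$excluded)) f$converged else NA, NA),
    excluded_reason = excluded, stringsAsFactors = FALSE)
  out$p_adj <- p.adjust(out$p, "BH")

  if (concordance && length(covariates)) {
    unadj <- run_de(expr, annotation, contrast_level, location,
                    covariates = character(0), random = random)
    sig_a <- out$gene_id[!is.na(out$p_adj) & out$p_adj < 0.05]
    sig_u <- unadj$gene_id[!is.na(unadj$p_adj) & unadj$p_adj < 0.05]
    either <- union(sig_a, sig_u)
    attr(out, "concordance") <- list(
      n_adjusted = length(sig_a), n_unadjusted = length(sig_u),
      n_both = length(intersect(sig_a, sig_u)),
      frac_both = if (length(either))
        length(intersect(sig_a, sig_u)) / length(either) else NA_real_)
  }
  out
}

interaction_group <- function(meta) {
  lab <- ifelse(meta$disease == "HC", "HC-noninf",
                paste0(meta$disease,
                       ifelse(meta$inflamed == "yes", "-inf", "-noninf")))
  factor(lab, levels = c("HC-noninf", "UC-noninf", "UC-inf",
                         "CD-noninf", "CD-inf"))
}

#' Call differentially expressed genes
#'
#' DE requires adjusted p below \code{alpha} and |log2 fold-change| strictly
#' above \code{min_abs_lfc}; calls are signed into up/down sets. A stricter
#' fold-change cutoff (e.g. 1.5) can be passed for selection-style analyses.
#'
#' @param results \code{\link{run_de}} table.
#' @param alpha adjusted-p threshold (strict <).
#' @param min_abs_lfc log2 fold-change threshold (strict >).
#' @return list with character vectors \code{up} and \code{down}.
#' @export
call_de <- function(results, alpha = 0.05, min_abs_lfc = 1.0) {
  ok <- !is.na(results$p_adj) & results$p_adj < alpha &
    abs(results$lfc) > min_abs_lfc
  list(up = results$gene_id[ok & results$lfc > 0],
       down = results$gene_id[ok & results$lfc < 0])
}

#' Venn-region cardinalities for named DE gene sets
#'
#' @param sets named list (>= 2) of gene id vectors.
#' @return data.frame with one row per nonempty membership pattern: logical
#'   membership columns and the exclusive region size \code{n}.
#' @export
de_overlap <- function(sets) {
  if (length(sets) < 2) stop("need >= 2 sets")
  universe <- unique(unlist(sets))
  member <- vapply(sets, function(s) universe %in% s, logical(length(universe)))
  if (length(universe) == 1) member <- matrix(member, nrow = 1,
                                              dimnames = list(NULL, names(sets)))
  patterns <- expand.grid(rep(list(c(TRUE, FALSE)), length(sets)))
  names(patterns) <- names(sets)
  patterns <- patterns[rowSums(patterns) > 0, , drop = FALSE]
  patterns$n <- apply(patterns, 1, function(p)
    sum(apply(member, 1, function(m) all(m == as.logical(p)))))
  rownames(patterns) <- NULL
  patterns
}
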