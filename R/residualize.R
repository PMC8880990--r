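#' Protein matrices with preprocessing-stage tracking
#'
#' Tags a wide sample-by-protein table with its preprocessing stage. The
#' pipeline enforces the one-way progression
#' `raw -> int_transformed -> residualized`: levels are first mapped to
#' normal quantiles by [rank_inverse_normal()], then regressed on covariates
#' and known pQTL dosages, and only the residuals are used as training
#' outcomes.
#'
#' @param data Wide data frame (first column sample IDs) or numeric matrix
#'   with sample-ID rownames.
#' @param stage One of `"raw"`, `"int_transformed"`, `"residualized"`.
#' @param panel Optional analyte-panel tag (e.g. `"somascan"`, `"olink"`)
#'   recorded in downstream weight files.
#' @return A tibble with attributes `stage` and `panel`.
#' @export
protein_matrix <- function(data, stage = c("raw", "int_transformed", "residualized"),
                           panel = "unknown") {
  stage <- match.arg(stage)
  m <- as_sample_matrix(data, "protein matrix")
  out <- matrix_to_tibble(m)
  attr(out, "stage") <- stage
  attr(out, "panel") <- panel
  out
}

protein_stage <- function(x) attr(x, "stage") %||% "raw"

#' Apply rank-based inverse normalisation to every protein column
#'
#' @param proteins A `raw`-stage table from [protein_matrix()] (a plain data
#'   frame is treated as raw).
#' @param offset Rank offset passed to [rank_inverse_normal()].
#' @return The table at stage `int_transformed`.
#' @export
int_transform_proteins <- function(proteins, offset = 3 / 8) {
  if (protein_stage(proteins) != "raw") {
    abort(sprintf("int_transform_proteins: expected stage 'raw', got '%s'",
                  protein_stage(proteins)))
  }
  panel <- attr(proteins, "panel") %||% "unknown"
  m <- as_sample_matrix(proteins, "protein matrix")
  dn <- dimnames(m)
  m <- apply(m, 2, rank_inverse_normal, offset = offset)
  dimnames(m) <- dn
  protein_matrix(m, stage = "int_transformed", panel = panel)
}

#' A pQTL map linking proteins to genotype-dosage columns
#'
#' @param map Data frame with columns `protein_id` and `variant_id`, one row
#'   per (protein, variant) link. Proteins absent from the map simply have no
#'   pQTL adjustment.
#' @return A tibble of class `pqtl_map`.
#' @export
pqtl_map <- function(map) {
  if (!all(c("protein_id", "variant_id") %in% names(map))) {
    abort("pqtl_map: need columns protein_id and variant_id")
  }
  out <- as_tibble(map[c("protein_id", "variant_id")])
  class(out) <- c("pqtl_map", class(out))
  out
}

# Full-rank indicator expansion of a covariate table (no intercept column;
# one is added by the residualizer). Errors name collinear columns.
expand_covariates <- function(covariates, id_col = "sample_id") {
  ids <- as.character(covariates[[id_col]])
  if (anyDuplicated(ids) > 0) abort("covariate table: duplicate sample identifiers")
  df <- covariates[setdiff(names(covariates), id_col)]
  df <- as.data.frame(lapply(df, function(col) {
    if (is.character(col) || is.logical(col)) factor(col) else col
  }), check.names = FALSE)
  X <- if (ncol(df) == 0) {
    matrix(numeric(0), nrow = length(ids), ncol = 0)
  } else {
    stats::model.matrix(~ ., data = df)[, -1, drop = FALSE]
  }
  rownames(X) <- ids
  X
}

#' Residualize protein levels on covariates and known pQTLs
#'
#' Regresses each INT-transformed protein column on an intercept, the shared
#' covariate design (categorical columns expanded to full-rank indicators)
#' and, where the pQTL map lists variants for that protein, the corresponding
#' genotype-dosage columns. Returns the least-squares residuals, which are
#' orthogonal to every design column and mean zero.
#'
#' @param proteins Table at stage `int_transformed` (see
#'   [int_transform_proteins()]).
#' @param covariates Data frame with a `sample_id` column plus covariate
#'   columns (age, sex, genetic PCs, batch, ...). May be `NULL` for an
#'   intercept-only design, in which case residualization is mean-centering.
#' @param pqtls Optional [pqtl_map()].
#' @param genotypes Optional wide dosage table (sample_id + variant columns,
#'   additive dosages in `[0, 2]`); required when `pqtls` is given.
#' @return Protein table at stage `residualized`.
#' @export
residualize_proteins <- function(proteins, covariates = NULL, pqtls = NULL,
                                 genotypes = NULL) {
  if (protein_stage(proteins) != "int_transformed") {
    abort(sprintf("residualize_proteins: expected stage 'int_transformed', got '%s'",
                  protein_stage(proteins)))
  }
  panel <- attr(proteins, "panel") %||% "unknown"
  Y <- as_sample_matrix(proteins, "protein matrix")
  n <- nrow(Y)

  C <- if (is.null(covariates)) {
    matrix(numeric(0), nrow = n, ncol = 0, dimnames = list(rownames(Y), NULL))
  } else {
    expand_covariates(covariates)
  }
  if (!is.null(covariates)) {
    if (!all(rownames(Y) %in% rownames(C))) {
      abort("residualize_proteins: sample mismatch between protein and covariate tables")
    }
    C <- C[rownames(Y), , drop = FALSE]
  }

  G <- NULL
  if (!is.null(pqtls)) {
    if (is.null(genotypes)) abort("residualize_proteins: pqtls given without genotypes")
    G <- as_sample_matrix(genotypes, "genotype table")
    if (!all(rownames(Y) %in% rownames(G))) {
      abort("residualize_proteins: sample mismatch between protein and genotype tables")
    }
    G <- G[rownames(Y), , drop = FALSE]
    missing_var <- setdiff(unique(pqtls$variant_id), colnames(G))
    if (length(missing_var)) {
      abort(sprintf("residualize_proteins: pQTL variants absent from genotype table: %s",
                    paste(missing_var, collapse = ", ")))
    }
  }

  base <- cbind(`(Intercept)` = rep(1, n), C)
  check_design_rank(base, "shared covariate design")

  out <- Y
  for (prot in colnames(Y)) {
    X <- base
    if (!is.null(pqtls)) {
      vars <- pqtls$variant_id[pqtls$protein_id == prot]
      if (length(vars)) X <- cbind(X, G[, vars, drop = FALSE])
    }
    check_design_rank(X, sprintf("design for protein '%s'", prot))
    fit <- lm.fit(X, Y[, prot])
    out[, prot] <- fit$residuals
  }
  protein_matrix(out, stage = "residualized", panel = panel)
}

check_design_rank <- function(X, what) {
  if (ncol(X) == 0) return(invisible(X))
  q <- qr(X)
  if (q$rank < ncol(X)) {
    dropped <- colnames(X)[q$pivot[(q$rank + 1):ncol(X)]]
    abort(sprintf("rank-deficient %s: collinear columns %s", what,
                  paste(dropped, collapse = ", ")))
  }
  invisible(X)
}
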