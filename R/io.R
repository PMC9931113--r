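# Serialisation: dataset CSVs (exact round trip), YAML/JSON model specs, and
# JSON results with embedded provenance (seed, config, package version).

#' Write / read a grouped design as CSV
#'
#' Columns are `y`, `group`, optionally `t`, then `x_1..x_d` and `z_1..z_m`.
#' Numeric values are written with 17 significant digits so the written file
#' reads back bit-identically.
#'
#' @param design A [grouped_design()].
#' @param path CSV path.
#' @return `write_dataset_csv()` the path, invisibly; `read_dataset_csv()` a
#'   [grouped_design()].
#' @export
write_dataset_csv <- function(design, path) {
  stopifnot(inherits(design, "grouped_design"))
  fmt <- function(x) sprintf("%.17g", x)
  df <- data.frame(y = fmt(design$y),
                   group = design$group_labels[design$group],
                   stringsAsFactors = FALSE)
  if (!is.null(design$t)) df$t <- fmt(design$t)
  for (j in seq_len(design$d)) df[[paste0("x_", j)]] <- fmt(design$X[, j])
  if (design$m > 0L) {
    for (j in seq_len(design$m)) df[[paste0("z_", j)]] <- fmt(design$Z[, j])
  }
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_dataset_csv
#' @export
read_dataset_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  xcols <- grep("^x_[0-9]+$", names(df), value = TRUE)
  zcols <- grep("^z_[0-9]+$", names(df), value = TRUE)
  if (!("y" %in% names(df)) || length(xcols) == 0L) {
    stop_input("dataset CSV must contain `y` and `x_*` columns")
  }
  xcols <- xcols[order(as.integer(sub("x_", "", xcols)))]
  zcols <- zcols[order(as.integer(sub("z_", "", zcols)))]
  grouped_design(
    y = as.numeric(df$y),
    X = as.matrix(vapply(df[xcols], as.numeric, numeric(nrow(df)))),
    Z = if (length(zcols)) as.matrix(vapply(df[zcols], as.numeric, numeric(nrow(df)))),
    group = if ("group" %in% names(df)) df$group,
    t = if ("t" %in% names(df)) as.numeric(df$t)
  )
}

# Expand a spec-file covariance entry into a matrix.
parse_cov <- function(cov, d = NULL) {
  if (is.list(cov) && !is.null(cov$identity)) return(diag(as.integer(cov$identity)))
  if (is.numeric(cov) && is.null(dim(cov))) {
    if (length(cov) == 1L && !is.null(d)) return(diag(as.numeric(cov), d))
    return(diag(as.numeric(cov)))
  }
  m <- if (is.list(cov)) do.call(rbind, lapply(cov, as.numeric)) else as.matrix(cov)
  m
}

#' Read a model specification from YAML or JSON
#'
#' Schema (YAML shown; JSON is isomorphic):
#' ```yaml
#' kind: linear            # linear | linear_nig | multilevel_intercept | multilevel_general
#' name: M0                # optional
#' coef_prior:
#'   mean: 0               # scalar (recycled) or vector
#'   cov: [1, 4, 5]        # vector = diagonal; nested lists = full matrix;
#'                         # {identity: d} = identity of dimension d
#' variance_priors:        # inverse-gamma {shape, scale} per component
#'   sigma2: {shape: 3, scale: 0.4}
#'   # sigma2_y / sigma2_eta for multilevel_intercept
#'   # sigma2_y plus nu: [{shape,scale}, ...] for multilevel_general
#' nig: {shape: 3, scale: 0.4, gamma: 5}    # linear_nig only
#' structure:              # multilevel_general only
#'   kind: pair_correlation
#'   m: 2
#'   rho: 0.2              # fixed value (banded_shared_rho); omit if free
#'   rho_prior: {mean: 0, sd: 1}
#' ```
#'
#' @param path File path ending in `.yaml`/`.yml` or `.json`.
#' @param d Coefficient dimension, required when the prior covariance is
#'   given as a scalar.
#' @return A [model_spec()].
#' @export
read_model_spec <- function(path, d = NULL) {
  obj <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  kind <- obj$kind %||% stop_input("model spec lacks `kind`")
  igp <- function(x) invgamma_prior(x$shape, x$scale)
  if (kind == "linear_nig") {
    ni <- obj$nig %||% stop_input("linear_nig spec needs an `nig` block")
    cov <- parse_cov(obj$coef_prior$cov, d)
    prior <- nig_prior(ni$shape, ni$scale, obj$coef_prior$mean %||% 0, cov,
                       gamma = ni$gamma %||% 1)
    return(model_spec(kind, prior, name = obj$name))
  }
  cov <- parse_cov(obj$coef_prior$cov, d)
  prior <- gaussian_prior(obj$coef_prior$mean %||% 0, cov)
  vp <- obj$variance_priors
  if (kind == "linear") {
    return(model_spec(kind, prior, list(sigma2 = igp(vp$sigma2)), name = obj$name))
  }
  if (kind == "multilevel_intercept") {
    return(model_spec(kind, prior,
                      list(sigma2_y = igp(vp$sigma2_y), sigma2_eta = igp(vp$sigma2_eta)),
                      name = obj$name))
  }
  st <- obj$structure %||% stop_input("multilevel_general spec needs a `structure` block")
  structure_obj <- cov_structure(st$kind, m = st$m, rho = st$rho,
                                 rho_prior = st$rho_prior)
  nu_list <- if (is.data.frame(vp$nu)) {
    lapply(seq_len(nrow(vp$nu)), function(i) igp(vp$nu[i, ]))
  } else {
    lapply(vp$nu, igp)
  }
  model_spec(kind, prior,
             list(sigma2_y = igp(vp$sigma2_y), nu = nu_list),
             structure = structure_obj, name = obj$name)
}

#' Write an analysis result as JSON with provenance
#'
#' Every artefact embeds the seed, the configuration used, the package
#' version and a schema identifier; [validate_results_json()] checks the
#' shipped schema (`inst/schema/results-v1.json`).
#'
#' @param x A data frame or list of results.
#' @param path Output JSON path.
#' @param seed The seed the results were produced under.
#' @param config Configuration list to embed.
#' @return The path, invisibly.
#' @export
write_results_json <- function(x, path, seed, config = list()) {
  payload <- list(
    schema = "intlik/results-v1",
    package_version = as.character(packageVersion("intlik")),
    seed = seed,
    config = config,
    results = x
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_results_json
#' @param strict Error (rather than return `FALSE`) on failure?
#' @export
validate_results_json <- function(path, strict = TRUE) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  required <- c("schema", "package_version", "seed", "results")
  missing <- setdiff(required, names(obj))
  ok <- length(missing) == 0L && identical(obj$schema, "intlik/results-v1")
  if (!ok && strict) {
    stop_input("results JSON invalid: missing %s",
               paste(c(missing, if (!identical(obj$schema, "intlik/results-v1")) "valid schema id"),
                     collapse = ", "))
  }
  ok
}
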