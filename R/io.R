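#' Read and write planar biaxial CSV files
#'
#' Interchange format for biaxial stress-stretch records: a CSV with header
#' `protocol,lambda_theta,lambda_z,sigma_theta_kpa,sigma_z_kpa`. Reading
#' validates every row (positive finite stretches, finite stresses) and
#' reports offending line numbers; writing is the exact inverse.
#'
#' @param path File path.
#' @param structure A [structural_constants()] object to attach (required
#'   for fitting; may be `NULL` when only the records are needed).
#' @param specimen_id Optional specimen label.
#' @return `read_biaxial_csv()`: a [biaxial_dataset()] (or a bare data frame
#'   when `structure` is `NULL`). `write_biaxial_csv()`: the path, invisibly.
#' @export
read_biaxial_csv <- function(path, structure = NULL, specimen_id = NULL) {
  need <- c("protocol", "lambda_theta", "lambda_z",
            "sigma_theta_kpa", "sigma_z_kpa")
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("schema error in ", path, ": missing column(s) ",
         paste(miss, collapse = ", "))
  num <- need[-1]
  for (cn in num) df[[cn]] <- suppressWarnings(as.numeric(df[[cn]]))
  bad <- !stats::complete.cases(df[num]) |
    df$lambda_theta <= 0 | df$lambda_z <= 0
  if (any(bad))
    stop("malformed biaxial rows in ", path, " at line(s): ",
         paste(utils::head(which(bad) + 1L, 10L), collapse = ", "))
  recs <- data.frame(protocol = df$protocol,
                     lambda_theta = df$lambda_theta,
                     lambda_z = df$lambda_z,
                     sigma_theta = df$sigma_theta_kpa,
                     sigma_z = df$sigma_z_kpa)
  if (is.null(structure)) return(recs)
  biaxial_dataset(recs, structure, specimen_id)
}

#' @rdname read_biaxial_csv
#' @param dataset A [biaxial_dataset()] or compatible data frame.
#' @export
write_biaxial_csv <- function(dataset, path) {
  df <- data.frame(protocol = dataset$protocol,
                   lambda_theta = dataset$lambda_theta,
                   lambda_z = dataset$lambda_z,
                   sigma_theta_kpa = dataset$sigma_theta,
                   sigma_z_kpa = dataset$sigma_z)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a grayscale TIFF image stack
#'
#' Reads a single- or multi-page grayscale TIFF into a list of intensity
#' matrices in page order. RGB input is rejected with instructions to
#' select a channel first.
#'
#' @param path TIFF file path.
#' @param plane Plane label attached to each image (`"in_plane"` or
#'   `"out_of_plane"`).
#' @return List of numeric matrices with attribute `plane`.
#' @export
read_image_stack <- function(path, plane = c("in_plane", "out_of_plane")) {
  plane <- match.arg(plane)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) == 0L) stop("empty TIFF: ", path)
  lapply(pages, function(p) {
    if (length(dim(p)) == 3L) {
      if (dim(p)[3] > 1L)
        stop("RGB/multichannel TIFF: extract a single grayscale channel ",
             "before analysis")
      p <- p[, , 1L]
    }
    attr(p, "plane") <- plane
    p
  })
}

#' @rdname read_image_stack
#' @param images List of numeric matrices with intensities in `[0, 1]`
#'   (rescaled if not).
#' @export
write_image_stack <- function(images, path) {
  if (is.matrix(images)) images <- list(images)
  images <- lapply(images, function(m) {
    m <- as.matrix(m)
    mx <- max(m)
    if (mx > 1) m <- m / mx
    pmin(pmax(m, 0), 1)
  })
  tiff::writeTIFF(images, path, bits.per.sample = 16L)
  invisible(path)
}

#' Write a specimen dispersion report as JSON
#'
#' Serializes a `dispersion_set` (from [aggregate_stack()] or
#' [stack_pipeline()]) to the per-stack JSON report schema:
#' `alpha_deg`, `alpha_sd_deg`, `kappa_ip`, `kappa_op`, `a_mean`, `b_mean`,
#' `n_images`, `n_isotropic`.
#'
#' @param ds A `dispersion_set`.
#' @param path Output JSON path.
#' @return The path, invisibly.
#' @export
write_dispersion_report <- function(ds, path) {
  stopifnot(inherits(ds, "dispersion_set"))
  jsonlite::write_json(unclass(ds)[c("alpha_deg", "alpha_sd_deg", "kappa_ip",
                                     "kappa_op", "a_mean", "b_mean",
                                     "n_images", "n_isotropic")],
                       path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' Read a dispersion report back into structural constants
#'
#' @param path JSON path written by [write_dispersion_report()].
#' @return A [structural_constants()] object.
#' @export
read_dispersion_report <- function(path) {
  rep <- jsonlite::read_json(path, simplifyVector = TRUE)
  structural_constants(rep$alpha_deg, rep$kappa_ip, rep$kappa_op)
}

#' Run the structure-to-stress pipeline from a configuration
#'
#' Executes the configured stages end to end: image stacks to structural
#' parameters (`orient`), biaxial CSV plus structure to a constitutive fit
#' (`fit`, with optional bootstrap), and a cohort table to summary
#' statistics (`cohort`). The configuration is a named list or the path to
#' a YAML file with any of the blocks:
#'
#' * `orient`: `in_plane` (TIFF path), optional `out_of_plane`, optional
#'   `wedge_width`, `isotropy_r2`; the resulting report is written to
#'   `<out>/dispersion.json`.
#' * `fit`: `data` (biaxial CSV), `model`, and either `structure` (path to
#'   a dispersion JSON) or the `orient` result; optional `n_starts`,
#'   `bootstrap` (iteration count) and `seed`; writes `<out>/fit.json`.
#' * `cohort`: `table` (CSV path); writes `<out>/cohort.json`.
#' * `out`: output directory (default `"."`); `seed`: global seed.
#'
#' All randomness flows from the configured seed; rerunning with the same
#' config and inputs reproduces the same results.
#'
#' @param config Named list or YAML file path.
#' @return A list with the results of each configured stage, invisibly.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  out_dir <- config$out %||% "."
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  seed <- config$seed
  results <- list()

  if (!is.null(config$orient)) {
    oc <- config$orient
    if (is.null(oc$in_plane)) stop("orient stage needs an in_plane stack path")
    ip <- read_image_stack(oc$in_plane, "in_plane")
    op <- if (!is.null(oc$out_of_plane))
      read_image_stack(oc$out_of_plane, "out_of_plane") else list()
    ds <- stack_pipeline(ip, op,
                         wedge_width = oc$wedge_width %||% 5,
                         isotropy_r2 = oc$isotropy_r2 %||% 0.9998)
    write_dispersion_report(ds, file.path(out_dir, "dispersion.json"))
    results$orient <- ds
  }

  if (!is.null(config$fit)) {
    fc <- config$fit
    if (is.null(fc$data)) stop("fit stage needs a biaxial CSV path")
    sc <- if (!is.null(fc$structure)) read_dispersion_report(fc$structure)
      else if (!is.null(results$orient))
        structural_constants(results$orient$alpha_deg,
                             results$orient$kappa_ip,
                             results$orient$kappa_op)
      else stop("fit stage needs structure (path or orient stage)")
    dat <- read_biaxial_csv(fc$data, sc)
    fit <- fiber_fit(dat, fc$model %||% "two_fiber",
                     n_starts = fc$n_starts %||% 20,
                     seed = fc$seed %||% seed)
    if (!is.null(fc$bootstrap))
      fit <- bootstrap_fit(fit, n_iter = fc$bootstrap,
                           seed = fc$seed %||% seed)
    rec <- c(as.list(fit$params),
             list(r2_theta = fit$r2[["r2_theta"]], r2_z = fit$r2[["r2_z"]],
                  sse = fit$sse, model = fit$model,
                  n_points = fit$n_points,
                  alpha_deg = sc$alpha_deg, kappa_ip = sc$kappa_ip,
                  kappa_op = sc$kappa_op))
    if (!is.null(fit$boot_estimate))
      rec$bootstrap_estimate <- as.list(fit$boot_estimate)
    jsonlite::write_json(rec, file.path(out_dir, "fit.json"),
                         auto_unbox = TRUE, digits = NA)
    results$fit <- fit
  }

  if (!is.null(config$cohort)) {
    cc <- config$cohort
    if (is.null(cc$table)) stop("cohort stage needs a table path")
    tab <- utils::read.csv(cc$table, stringsAsFactors = FALSE)
    summ <- cohort_summary(tab)
    trends <- lapply(intersect(c("alpha_deg", "kappa_ip", "kappa_op"),
                               names(tab)), function(f) {
      tr <- pearson_with_age(tab, f)
      list(field = f, r = tr$r, p = tr$p, slope = tr$slope,
           intercept = tr$intercept, n = tr$n)
    })
    payload <- list(age_mean = summ$age_mean, age_sd = summ$age_sd,
                    n = summ$n, r2 = summ$r2, trends = trends)
    jsonlite::write_json(payload, file.path(out_dir, "cohort.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
    results$cohort <- payload
  }

  invisible(results)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
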