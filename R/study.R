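# End-to-end phantom study: generate synthetic "patients", corrupt the
# ground-truth fields inside organs, apply the hybrid FEM correction (and
# optionally the contour-matching registration), and summarize per-organ
# DSC / MDA / STD-JD with one-tailed WMW comparisons -- the same
# comparison design used to benchmark DIR algorithms against their FEM
# modifications on patient data.

study_ground_truth <- function(i, rng) {
  # alternate translations and mild affine deformations, all <= ~8 mm
  t0 <- round(2 * (2 * rng(3) - 1) + c(5, -4, 3) * (1 - 2 * (i %% 2)), 2)
  if (i %% 2 == 1L)
    list(kind = "translation", params = list(t = t0))
  else {
    A <- diag(round(0.04 * (2 * rng(3) - 1), 3)) +
      matrix(round(0.015 * (2 * rng(9) - 1), 3), 3, 3)
    diag(A) <- diag(A) + c(0.03, -0.02, 0.025)
    list(kind = "affine",
         params = list(A = A, b = t0, center = c(64, 64, 64)))
  }
}

#' Run the synthetic correction study
#'
#' Generates `n_phantoms` phantom anatomies, deforms each by a known
#' smooth transform, corrupts the ground-truth field with interior bumps
#' (boundary displacements untouched), applies the hybrid FEM correction,
#' and evaluates DSC, MDA and STD-JD per organ before and after
#' correction; optionally the CM-FEM registration is run as an independent
#' method. Cohort columns are compared with one-tailed WMW tests in the
#' improvement direction (smaller STD-JD / MDA, larger DSC).
#'
#' @param n_phantoms number of phantom "patients" (3 organs each).
#' @param seed integer master seed; fixes anatomies, deformations and
#'   corruption.
#' @param mesh_divisions correction-mesh resolution (cubes per axis).
#' @param margin_mm mesh margin (mm).
#' @param corruption a [corruption_spec()]; its seed field is re-derived
#'   from `seed` per phantom.
#' @param include_cmfem also run the contour-matching registration.
#' @param cfg [match_config()] for the CM-FEM arm.
#' @param verbose narrate pipeline stages via `message()`.
#' @return A `study_report`: list with `per_organ` (long data.frame),
#'   `summary` (per-method mean +/- sd), `p_values`, `std_jd_reduction_pct`
#'   and `config`.
#' @export
run_study <- function(n_phantoms = 7, seed = 1, mesh_divisions = 12,
                      margin_mm = 10, corruption = corruption_spec(),
                      include_cmfem = FALSE, cfg = match_config(),
                      verbose = FALSE) {
  say <- function(...) if (verbose) message(...)
  rows <- list()
  for (i in seq_len(n_phantoms)) {
    say("phantom ", i, "/", n_phantoms)
    ph <- make_phantom(phantom_spec(seed = seed * 1000L + i))
    rng <- rng_stream(seed * 1000L + i, 733L)
    gt <- study_ground_truth(i, rng)
    def <- deform_phantom(ph, gt$kind, gt$params)
    organ_labels <- ph$spec$organs$label
    cor_spec <- corruption
    cor_spec$seed <- seed * 1000L + i
    corrupted <- suppressWarnings(corrupt_field(def$field, ph$labels, cor_spec))
    say("  corrupted STD-JD: ",
        paste(signif(attr(corrupted, "achieved_std_jd"), 3), collapse = " "))
    corrected <- suppressMessages(
      correct_field(corrupted, ph$labels, organ_labels, ph$materials,
                    mesh_divisions, margin_mm))
    fields <- list(preliminary = corrupted, hybrid_fem = corrected)
    if (include_cmfem) {
      say("  CM-FEM registration")
      fields$cm_fem <- suppressMessages(
        register_cmfem(ph$structures, def$structures, ph$labels,
                       ph$materials, cfg, mesh_divisions, margin_mm))
    }
    for (method in names(fields)) {
      rep <- evaluate_registration(fields[[method]], ph$structures,
                                   def$structures)
      rep$phantom <- i
      rep$method <- method
      rows[[length(rows) + 1L]] <- rep
    }
  }
  per_organ <- do.call(rbind, lapply(rows, as.data.frame))
  rownames(per_organ) <- NULL
  meth <- unique(per_organ$method)
  summ <- do.call(rbind, lapply(meth, function(m) {
    d <- per_organ[per_organ$method == m, ]
    data.frame(method = m,
               dsc_mean = mean(d$dsc), dsc_sd = stats::sd(d$dsc),
               mda_mean = mean(d$mda), mda_sd = stats::sd(d$mda),
               std_jd_mean = mean(d$std_jd), std_jd_sd = stats::sd(d$std_jd),
               n_organs = nrow(d))
  }))
  pre <- per_organ[per_organ$method == "preliminary", ]
  post <- per_organ[per_organ$method == "hybrid_fem", ]
  p_values <- data.frame(
    metric = c("std_jd", "dsc", "mda"),
    alternative = c("less", "greater", "less"),
    p = c(wmw_one_tailed(post$std_jd, pre$std_jd, "less"),
          wmw_one_tailed(post$dsc, pre$dsc, "greater"),
          wmw_one_tailed(post$mda, pre$mda, "less")))
  reduction <- 100 * (mean(pre$std_jd) - mean(post$std_jd)) /
    mean(pre$std_jd)
  structure(list(per_organ = per_organ, summary = summ, p_values = p_values,
                 std_jd_reduction_pct = reduction,
                 config = list(n_phantoms = n_phantoms, seed = seed,
                               mesh_divisions = mesh_divisions,
                               margin_mm = margin_mm,
                               corruption = unclass(corruption),
                               include_cmfem = include_cmfem)),
            class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("Phantom correction study: %d phantoms, %d organs per method\n",
              x$config$n_phantoms, x$summary$n_organs[1]))
  s <- x$summary
  cat(sprintf("%-12s %-14s %-16s %-14s\n", "method", "DSC", "MDA (mm)",
              "STD-JD"))
  for (i in seq_len(nrow(s)))
    cat(sprintf("%-12s %.2f +/- %.2f  %.2f +/- %.2f mm  %.3f +/- %.3f\n",
                s$method[i], s$dsc_mean[i], s$dsc_sd[i], s$mda_mean[i],
                s$mda_sd[i], s$std_jd_mean[i], s$std_jd_sd[i]))
  cat(sprintf("hybrid correction reduces mean STD-JD by %.1f%%\n",
              x$std_jd_reduction_pct))
  p <- x$p_values
  cat("one-tailed WMW p (hybrid vs preliminary): ",
      paste(sprintf("%s %.4g", p$metric, p$p), collapse = ", "), "\n",
      sep = "")
  invisible(x)
}

#' @export
plot.study_report <- function(x, metric = c("std_jd", "dsc", "mda"), ...) {
  metric <- match.arg(metric)
  graphics::boxplot(x$per_organ[[metric]] ~ x$per_organ$method,
                    xlab = "method", ylab = metric, ...)
  invisible(x)
}

#' Write provenance metadata for a run
#'
#' Serializes the run configuration, seeds and library versions to
#' `provenance.json` inside `dir`.
#'
#' @param dir output directory (created if missing).
#' @param config named list describing the run.
#' @return Path of the written file, invisibly.
#' @export
write_provenance <- function(dir, config) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  path <- file.path(dir, "provenance.json")
  info <- list(
    config = config,
    r_version = R.version.string,
    package_versions = list(
      dvfmend = as.character(utils::packageVersion("dvfmend")),
      Matrix = as.character(utils::packageVersion("Matrix")),
      RNifti = as.character(utils::packageVersion("RNifti"))),
    timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(info, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read / write a material table as JSON
#'
#' @param table a [material_table()].
#' @param path JSON file path.
#' @return `read_materials_json` returns a `material_table`.
#' @export
write_materials_json <- function(table, path) {
  jsonlite::write_json(as.data.frame(table), path, dataframe = "rows",
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_materials_json
#' @export
read_materials_json <- function(path) {
  d <- jsonlite::read_json(path, simplifyVector = TRUE)
  material_table(label = d$label, name = d$name, E = d$E, nu = d$nu)
}
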