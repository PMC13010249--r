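# File I/O and the staged experiment workflow: read/write reflectivity
# text files and structure configs, run the characterize -> inject ->
# refit sequence, and bundle reports for exact re-runs.

#' Read a reflectivity text file
#'
#' Accepts 3- or 4-column whitespace- or comma-separated text
#' (Q, R, sigma_R and optionally sigma_Q), with \code{#} comment lines.
#' Header comments of the form \code{# key: value} are parsed; a
#' \code{contrast} key (D2O volume fraction) sets the dataset's solvent
#' contrast, as does the \code{contrast} argument. A fourth column
#' enables per-point resolution smearing.
#'
#' @param path File path.
#' @param contrast D2O fraction or [solvent_contrast()]; overrides any
#'   header value.
#' @param dq_over_q Constant resolution used when no fourth column is
#'   present.
#' @return [contrast_dataset()].
#' @export
read_reflectivity <- function(path, contrast = NULL, dq_over_q = 0.035) {
  if (!file.exists(path)) stop("cannot open file '", path, "'")
  lines <- readLines(path)
  is_comment <- grepl("^\\s*#", lines)
  header <- lines[is_comment]
  meta <- list()
  for (h in header) {
    m <- regmatches(h, regexec("^\\s*#\\s*([A-Za-z_][A-Za-z0-9_]*)\\s*:\\s*(\\S+)", h))[[1]]
    if (length(m) == 3) meta[[m[2]]] <- m[3]
  }
  body_idx <- which(!is_comment & nzchar(trimws(lines)))
  if (!length(body_idx)) stop("no data rows in ", path)
  fields <- strsplit(trimws(lines[body_idx]), "[,[:space:]]+")
  ncol <- length(fields[[1]])
  if (!ncol %in% c(3, 4)) {
    stop(sprintf("%s line %d: expected 3 or 4 columns, found %d",
                 path, body_idx[1], ncol))
  }
  vals <- matrix(NA_real_, nrow = length(fields), ncol = ncol)
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    if (length(f) != ncol) {
      stop(sprintf("%s line %d: expected %d columns, found %d",
                   path, body_idx[i], ncol, length(f)))
    }
    v <- suppressWarnings(as.numeric(f))
    if (any(is.na(v))) {
      stop(sprintf("%s line %d: non-numeric value", path, body_idx[i]))
    }
    vals[i, ] <- v
  }
  if (is.unsorted(vals[, 1], strictly = TRUE)) {
    stop(path, ": Q column must be strictly increasing")
  }
  if (any(vals[, 3] <= 0)) {
    bad <- body_idx[which(vals[, 3] <= 0)[1]]
    stop(sprintf("%s line %d: non-positive sigma_R", path, bad))
  }
  if (is.null(contrast)) {
    if (!is.null(meta$contrast)) contrast <- as.numeric(meta$contrast)
    else stop(path, ": no contrast in header; pass contrast=")
  }
  if (!is.null(meta$dq_over_q)) dq_over_q <- as.numeric(meta$dq_over_q)
  contrast_dataset(vals[, 1], vals[, 2], vals[, 3], contrast,
                   sigma_q = if (ncol == 4) vals[, 4] else NULL,
                   dq_over_q = dq_over_q,
                   label = if (!is.null(meta$label)) meta$label else NULL)
}

#' Write a reflectivity dataset as columnar text
#'
#' Full-precision 3- or 4-column output with a small \code{# key: value}
#' header carrying the contrast and resolution, round-trippable by
#' [read_reflectivity()].
#'
#' @param ds [contrast_dataset()].
#' @param path Output path.
#' @export
write_reflectivity <- function(ds, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# contrast: %.17g", ds$contrast$d2o_fraction),
    sprintf("# dq_over_q: %.17g", ds$dq_over_q),
    sprintf("# label: %s", gsub("\\s+", "_", ds$label)),
    if (is.null(ds$sigma_q)) "# columns: Q R sigma_R"
    else "# columns: Q R sigma_R sigma_Q"), con)
  m <- cbind(ds$q, ds$r, ds$sigma_r, ds$sigma_q)
  write.table(format(m, digits = 17, scientific = TRUE, trim = TRUE),
              con, row.names = FALSE, col.names = FALSE, quote = FALSE)
}

#' Write a volume-fraction profile as TSV
#'
#' @param profile [volume_fraction_profile()] output.
#' @param path Output path.
#' @export
write_profile <- function(profile, path) {
  write.table(profile, path, sep = "\t", row.names = FALSE, quote = FALSE)
}

#' Serialize / load a membrane structure as YAML
#'
#' @param s [membrane_structure()].
#' @param path File path.
#' @export
write_structure_config <- function(s, path) {
  x <- unclass(s)
  x$lipids <- as.list(as.data.frame(s$lipids))
  x$surface_layers <- as.list(as.data.frame(s$surface_layers))
  yaml::write_yaml(x, path)
}

#' @rdname write_structure_config
#' @return [membrane_structure()].
#' @export
read_structure_config <- function(path) {
  x <- yaml::read_yaml(path)
  lip <- as.data.frame(x$lipids, stringsAsFactors = FALSE)
  sl <- if (length(x$surface_layers$thickness)) {
    as.data.frame(x$surface_layers, stringsAsFactors = FALSE)
  } else NULL
  membrane_structure(
    lipids = lip, bcl2_fraction = x$bcl2_fraction,
    bcl2_component = x$bcl2_component, surface_layers = sl,
    oxide_thickness = x$oxide_thickness, oxide_hydration = x$oxide_hydration,
    water_gap = x$water_gap, head_thickness = x$head_thickness,
    tail_thickness = x$tail_thickness, head_hydration = x$head_hydration,
    lipid_coverage = x$lipid_coverage,
    substrate_roughness = x$substrate_roughness, roughness = x$roughness)
}

component_library_hash <- function(lib) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  dput(lapply(lib, unclass), file = tmp)
  unname(tools::md5sum(tmp))
}

#' Run the staged bilayer-then-protein workflow
#'
#' Mirrors the experimental sequence: the bare Bcl-2-containing bilayer
#' is characterized first (pre-injection fit), then the protein-bound
#' state is fitted with the pre-injection parameters as the constrained
#' starting model (lipid composition fixed; protein layers and, to
#' capture any protein-induced thickening, the chain-region thickness
#' freed). Emits both reports, the chain-thickness change, and
#' volume-fraction profiles for both states, together with everything
#' needed for an exact re-run (config, seeds, component-library hash).
#'
#' @param config List with elements: \code{pre_datasets} and
#'   \code{post_datasets} (lists of [contrast_dataset()] or of file
#'   paths), \code{structure} (starting [membrane_structure()] or YAML
#'   path; surface layers define the post-injection template),
#'   \code{free_pre} and \code{free_post} (named bound lists as in
#'   [fit_problem()]), optional \code{seed} (default 1),
#'   \code{control} (optimizer budget), \code{n_resamples} (bootstrap;
#'   0 to skip), \code{dz} (profile grid).
#' @return A results bundle (list). On a stage failure the bundle is
#'   marked \code{partial = TRUE} with the failing stage and cause.
#' @export
run_workflow <- function(config) {
  seed <- if (is.null(config$seed)) 1 else config$seed
  control <- if (is.null(config$control)) list() else config$control
  nres <- if (is.null(config$n_resamples)) 0 else config$n_resamples
  dz <- if (is.null(config$dz)) 0.5 else config$dz
  lib <- if (is.null(config$lib)) component_library() else config$lib

  load_group <- function(x) {
    lapply(x, function(d) if (inherits(d, "contrast_dataset")) d
           else read_reflectivity(d))
  }
  s0 <- config$structure
  if (is.character(s0)) s0 <- read_structure_config(s0)

  bundle <- list(config = config, seed = seed,
                 component_library_hash = component_library_hash(lib),
                 partial = FALSE)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      bundle$partial <<- TRUE
      bundle$failed_stage <<- name
      bundle$cause <<- conditionMessage(e)
      NULL
    })
  }

  pre <- stage("pre_fit", {
    s_pre <- s0
    s_pre$surface_layers <- s0$surface_layers[0, , drop = FALSE]
    s_pre$bcl2_fraction <- min(s0$bcl2_fraction, s_pre$lipid_coverage)
    fit(fit_problem(s_pre, load_group(config$pre_datasets), config$free_pre,
                    lib = lib), seed = seed, control = control)
  })
  if (is.null(pre)) return(bundle)
  bundle$pre_fit <- pre
  bundle$pre_profile <- volume_fraction_profile(pre$structure, dz = dz, lib = lib)

  post <- stage("post_fit", {
    s_post <- pre$structure
    s_post$surface_layers <- s0$surface_layers
    fit(fit_problem(s_post, load_group(config$post_datasets),
                    config$free_post, lib = lib),
        seed = seed + 1, control = control, start = pre$par)
  })
  if (is.null(post)) return(bundle)
  bundle$post_fit <- post
  bundle$post_profile <- volume_fraction_profile(post$structure, dz = dz,
                                                 lib = lib)
  bundle$delta_tail_thickness <-
    post$structure$tail_thickness - pre$structure$tail_thickness

  if (nres >= 20) {
    ci <- stage("bootstrap", {
      confidence_intervals(fit_problem(post$structure,
                                       load_group(config$post_datasets),
                                       config$free_post, lib = lib),
                           post, n_resamples = nres, seed = seed + 2)
    })
    bundle$post_ci <- ci
    bundle$report <- structure_report(post, ci)
  } else {
    bundle$report <- structure_report(post)
  }
  bundle
}
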