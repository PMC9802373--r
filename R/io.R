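#' Read and write extension traces
#'
#' Plain tab-separated text: comment headers `# rate_hz:`, `# force_pn:`,
#' `# sigma:`, then columns `time_s`, `z_nm` and optionally `state` (the
#' ground-truth state path of a synthetic trace). `read_trace()` validates
#' uniform, strictly increasing time stamps and finite extensions, reporting
#' malformed rows with their line numbers.
#'
#' @param path File path.
#' @param trace An [extension_trace()].
#' @param rate Acquisition rate (Hz) overriding the file header.
#' @return `read_trace()`: an `extension_trace`; `write_trace()`: the path,
#'   invisibly.
#' @export
read_trace <- function(path, rate = NULL) {
  lines <- readLines(path)
  hdr <- grep("^#", lines)
  meta <- list()
  for (h in hdr) {
    m <- regmatches(lines[h], regexec("^#\\s*([a-z_]+)\\s*:\\s*(\\S+)", lines[h]))[[1]]
    if (length(m) == 3) meta[[m[2]]] <- suppressWarnings(as.numeric(m[3]))
  }
  body <- lines[setdiff(seq_along(lines), hdr)]
  body <- body[nzchar(trimws(body))]
  if (!length(body)) stop("no data rows in ", path)
  first_data_line <- setdiff(seq_along(lines), hdr)[1]
  has_names <- grepl("^[a-zA-Z]", body[1])
  if (has_names) body <- body[-1]
  parts <- strsplit(body, "\t", fixed = TRUE)
  ncol <- lengths(parts)
  if (any(ncol < 2)) {
    bad <- which(ncol < 2)[1]
    stop("malformed row at line ", bad, " of the data block in ", path)
  }
  tm <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 1L)))
  z <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 2L)))
  bad <- which(!is.finite(tm) | !is.finite(z))
  if (length(bad)) {
    stop("non-finite value at data line ", bad[1], " in ", path)
  }
  st <- if (any(ncol >= 3)) {
    as.integer(vapply(parts, function(p) if (length(p) >= 3) p[3] else NA, ""))
  } else NULL
  r <- if (!is.null(rate)) rate else meta$rate_hz
  if (is.null(r) || !is.finite(r)) {
    stop("acquisition rate missing: no '# rate_hz:' header and no 'rate' ",
         "argument")
  }
  extension_trace(time = tm, z = z, rate = r,
                  force = if (is.null(meta$force_pn)) NA_real_ else meta$force_pn,
                  sigma = if (is.null(meta$sigma)) NA_real_ else meta$sigma,
                  provenance = path, state = st)
}

#' @rdname read_trace
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "extension_trace"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# rate_hz: %.10g", trace$rate), con)
  if (!is.na(trace$force)) {
    writeLines(sprintf("# force_pn: %.10g", trace$force), con)
  }
  if (!is.na(trace$sigma)) {
    writeLines(sprintf("# sigma: %.10g", trace$sigma), con)
  }
  df <- data.frame(time_s = sprintf("%.8g", trace$time),
                   z_nm = sprintf("%.8g", trace$z))
  if (!is.null(trace$state)) df$state <- trace$state
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write rotation curves
#'
#' Tab-separated text with headers `# force_pn:` and `# n_bp:`, columns
#' `sigma`, `z_nm`, `var_nm2`, `se_z`, `se_var`.
#'
#' @param curve A [rotation_curve()].
#' @param path File path.
#' @param params Elastic parameters used to rebuild the molecule on read.
#' @return `read_rotation_curve()`: a `rotation_curve`;
#'   `write_rotation_curve()`: the path, invisibly.
#' @export
write_rotation_curve <- function(curve, path) {
  stopifnot(inherits(curve, "rotation_curve"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# force_pn: %.10g", attr(curve, "force")), con)
  writeLines(sprintf("# n_bp: %d", round(attr(curve, "molecule")$n_bp)), con)
  df <- as.data.frame(curve)
  names(df) <- c("sigma", "z_nm", "var_nm2", "se_z", "se_var")
  write.table(format(df, digits = 10, trim = TRUE), con, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_rotation_curve
#' @export
read_rotation_curve <- function(path, params = elastic_params()) {
  lines <- readLines(path)
  hdr <- grep("^#", lines)
  meta <- list()
  for (h in hdr) {
    m <- regmatches(lines[h], regexec("^#\\s*([a-z_]+)\\s*:\\s*(\\S+)", lines[h]))[[1]]
    if (length(m) == 3) meta[[m[2]]] <- as.numeric(m[3])
  }
  df <- read.table(text = lines[setdiff(seq_along(lines), hdr)],
                   header = TRUE, sep = "\t")
  if (is.null(meta$force_pn) || is.null(meta$n_bp)) {
    stop("rotation-curve file lacks '# force_pn:' or '# n_bp:' header")
  }
  rotation_curve(sigma = df$sigma, z = df$z_nm, var_z = df$var_nm2,
                 se_z = df$se_z, se_var = df$se_var,
                 force = meta$force_pn,
                 molecule = molecule_spec(meta$n_bp, params))
}

#' Export a theoretical rotation curve in per-length units
#'
#' Writes the analytical curve as tab-separated text with a `# force_pN`
#' header and columns `sigma`, `mean_ext_frac`, `var_per_len_nm`.
#'
#' @param sigma Supercoiling-density grid.
#' @param force Force (pN).
#' @param params [elastic_params()].
#' @param path Output file.
#' @return The path, invisibly.
#' @export
export_theory_curve <- function(sigma, force, params = elastic_params(),
                                path) {
  df <- data.frame(sigma = sigma,
                   mean_ext_frac = mean_extension(sigma, force, params),
                   var_per_len_nm = extension_variance(sigma, force, params))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# force_pN: %.10g", force), con)
  write.table(format(df, digits = 10, trim = TRUE), con, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write chain conformations as XYZ text
#'
#' One bead per line (`B x y z`, nm) with the chain metadata (segment
#' length, linking difference, excluded diameter, base pairs) in the XYZ
#' comment line.
#'
#' @param chain A [dna_chain()].
#' @param path File path.
#' @param params Elastic parameters for the rebuilt chain.
#' @return `read_chain_xyz()`: a `dna_chain`; `write_chain_xyz()`: the
#'   path, invisibly.
#' @export
write_chain_xyz <- function(chain, path) {
  stopifnot(inherits(chain, "dna_chain"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(as.character(nrow(chain$positions)), con)
  writeLines(sprintf("a=%.10g delta_lk=%.10g excluded_diameter=%.10g n_bp=%d",
                     chain$a, chain$delta_lk, chain$excluded_diameter,
                     round(chain$n_bp)), con)
  writeLines(sprintf("B %.9f %.9f %.9f", chain$positions[, 1],
                     chain$positions[, 2], chain$positions[, 3]), con)
  invisible(path)
}

#' @rdname write_chain_xyz
#' @export
read_chain_xyz <- function(path, params = elastic_params()) {
  lines <- readLines(path)
  n <- as.integer(lines[1])
  kv <- strsplit(strsplit(trimws(lines[2]), "\\s+")[[1]], "=")
  meta <- setNames(as.numeric(vapply(kv, `[`, "", 2L)),
                   vapply(kv, `[`, "", 1L))
  pos <- do.call(rbind, lapply(lines[3:(2 + n)], function(l) {
    as.numeric(strsplit(trimws(l), "\\s+")[[1]][2:4])
  }))
  dna_chain(n_bp = meta[["n_bp"]], delta_lk = meta[["delta_lk"]],
            params = params, a = meta[["a"]],
            excluded_diameter = meta[["excluded_diameter"]],
            positions = pos)
}

#' Read and write flat key-value run configuration
#'
#' Plain text, one `key: value` per line; values are parsed as numbers when
#' possible. Round-trips losslessly for numeric and string scalars.
#'
#' @param config Named list of scalars.
#' @param path File path.
#' @return `read_config()`: named list; `write_config()`: the path,
#'   invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(is.list(config), !is.null(names(config)))
  vals <- vapply(config, function(v) {
    if (is.numeric(v)) sprintf("%.17g", v) else as.character(v)
  }, "")
  writeLines(paste0(names(config), ": ", vals), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^#", lines)]
  m <- regmatches(lines, regexec("^([^:]+):\\s*(.*)$", lines))
  out <- list()
  for (x in m) {
    if (length(x) != 3) stop("malformed config line: ", x[1])
    val <- x[3]
    num <- suppressWarnings(as.numeric(val))
    out[[trimws(x[2])]] <- if (!is.na(num)) num else val
  }
  out
}
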