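read_metadata_comments <- function(path) {
  lines <- readLines(path, warn = FALSE)
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (ln in meta_lines) {
    ln <- sub("^#+\\s*", "", ln)
    if (grepl("=", ln, fixed = TRUE)) {
      key <- trimws(sub("=.*$", "", ln))
      val <- trimws(sub("^[^=]*=", "", ln))
      meta[[key]] <- val
    }
  }
  meta
}

#' Write a FOF grid to CSV
#'
#' Layout mirrors the conventional published table: first header cell
#' `X\\Y [cm]`, remaining header cells the Y sides, one row per X side.
#' Metadata (`kind`, `beam_quality`, `convention`, `msr_side_cm`) travels in
#' leading `# key=value` comment lines.
#'
#' @param grid A [fof_grid()].
#' @param path Output CSV path.
#' @param extra_comments Optional character vector of additional comment
#'   lines (written verbatim after a `# `).
#' @return `path`, invisibly.
#' @export
write_fof_grid <- function(grid, path, extra_comments = character()) {
  stopifnot(inherits(grid, "fof_grid"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# kind=%s", grid$kind), con)
  writeLines(sprintf("# beam_quality=%s", grid$beam_quality), con)
  writeLines(sprintf("# msr_side_cm=%s", format(grid$msr_side_cm)), con)
  if (!is.null(grid$convention))
    writeLines(sprintf("# convention=%s", grid$convention), con)
  for (cm in extra_comments) writeLines(paste0("# ", cm), con)
  header <- paste(c("X\\Y [cm]", format(grid$y_sides_cm)), collapse = ",")
  writeLines(header, con)
  tv <- t(grid$values)               # rows become X
  for (i in seq_along(grid$x_sides_cm))
    writeLines(paste(c(format(grid$x_sides_cm[i]),
                       format(tv[i, ], digits = 15, trim = TRUE)),
                     collapse = ","), con)
  invisible(path)
}

#' Read a FOF grid from CSV
#'
#' Inverse of [write_fof_grid()]; values are restored bit-exactly for grids
#' written by this package.
#'
#' @param path CSV path in the grid dialect.
#' @return A [fof_grid()].
#' @export
read_fof_grid <- function(path) {
  meta <- read_metadata_comments(path)
  lines <- grep("^#", readLines(path, warn = FALSE), value = TRUE,
                invert = TRUE)
  lines <- lines[nzchar(trimws(lines))]
  header <- strsplit(lines[1L], ",", fixed = TRUE)[[1L]]
  if (!grepl("^X\\\\Y", header[1L]))
    stop("not a FOF grid CSV: first header cell must be 'X\\Y [cm]'",
         call. = FALSE)
  y_sides <- as.numeric(header[-1L])
  body <- strsplit(lines[-1L], ",", fixed = TRUE)
  x_sides <- vapply(body, function(r) as.numeric(r[1L]), numeric(1))
  vals_x_major <- t(vapply(body, function(r) as.numeric(r[-1L]),
                           numeric(length(y_sides))))
  kind <- meta$kind %||% "measured"
  fof_grid(t(vals_x_major), y_sides, x_sides, kind = kind,
           beam_quality = meta$beam_quality %||% "6X",
           msr_side_cm = as.numeric(meta$msr_side_cm %||% "4"),
           convention = meta$convention %||% "relative")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write an ESS sweep table to CSV
#'
#' Stores percent differences between calculated and measured output factors
#' for one field as a (possibly sparse) matrix over candidate ESS values:
#' first header cell `ESSy\\ESSx`, remaining header cells the ESSx values in
#' mm, one row per ESSy value.  Unevaluated combinations are empty cells.
#'
#' @param sweep A matrix (rows = ESSy, columns = ESSx) with `NA` for
#'   unevaluated cells; `dimnames` give the ESS values in mm.
#' @param path Output CSV path.
#' @param field Field label, e.g. `"4x0.5"` (Y x X, cm).
#' @param beam_quality Beam quality label.
#' @param extra_comments Additional comment lines.
#' @return `path`, invisibly.
#' @export
write_ess_sweep <- function(sweep, path, field, beam_quality = "6X",
                            extra_comments = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# field=%s", field), con)
  writeLines(sprintf("# beam_quality=%s", beam_quality), con)
  for (cm in extra_comments) writeLines(paste0("# ", cm), con)
  writeLines(paste(c("ESSy\\ESSx", colnames(sweep)), collapse = ","), con)
  for (i in seq_len(nrow(sweep))) {
    cells <- ifelse(is.na(sweep[i, ]), "",
                    format(sweep[i, ], digits = 15, trim = TRUE))
    writeLines(paste(c(rownames(sweep)[i], cells), collapse = ","), con)
  }
  invisible(path)
}

#' Read an ESS sweep table from CSV
#'
#' @param path CSV path in the sweep dialect of [write_ess_sweep()].
#' @return A list with `sweep` (numeric matrix, `NA` where unevaluated),
#'   `essx_mm`, `essy_mm` (axes), `field`, and `beam_quality`.
#' @export
read_ess_sweep <- function(path) {
  meta <- read_metadata_comments(path)
  lines <- grep("^#", readLines(path, warn = FALSE), value = TRUE,
                invert = TRUE)
  lines <- lines[nzchar(trimws(lines))]
  header <- strsplit(lines[1L], ",", fixed = TRUE)[[1L]]
  if (!grepl("^ESSy\\\\ESSx", header[1L]))
    stop("not an ESS sweep CSV: first header cell must be 'ESSy\\ESSx'",
         call. = FALSE)
  essx <- as.numeric(header[-1L])
  body <- strsplit(lines[-1L], ",", fixed = TRUE)
  essy <- vapply(body, function(r) as.numeric(r[1L]), numeric(1))
  sweep <- t(vapply(body, function(r) {
    r <- r[-1L]
    length(r) <- length(essx)            # pad trailing empties
    suppressWarnings(as.numeric(ifelse(nzchar(trimws(r)), r, NA)))
  }, numeric(length(essx))))
  dimnames(sweep) <- list(as.character(essy), as.character(essx))
  list(sweep = sweep, essx_mm = essx, essy_mm = essy,
       field = meta$field %||% "", beam_quality = meta$beam_quality %||% "6X")
}

#' Write a 1-D profile to CSV
#'
#' Dialect: header `position_mm,value`, with `# axis=`, `# field=`,
#' `# beam_quality=` metadata comment lines.
#'
#' @param profile A [beam_profile()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path) {
  stopifnot(inherits(profile, "beam_profile"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# axis=%s", profile$axis), con)
  if (!is.null(profile$meta$field))
    writeLines(sprintf("# field=%s", profile$meta$field), con)
  if (!is.null(profile$meta$beam_quality))
    writeLines(sprintf("# beam_quality=%s", profile$meta$beam_quality), con)
  writeLines("position_mm,value", con)
  writeLines(paste(format(profile$positions_mm, digits = 15, trim = TRUE),
                   format(profile$values, digits = 15, trim = TRUE),
                   sep = ","), con)
  invisible(path)
}

#' Read a 1-D profile from CSV
#'
#' @param path CSV path in the dialect of [write_profile()].
#' @return A [beam_profile()].
#' @export
read_profile <- function(path) {
  meta <- read_metadata_comments(path)
  df <- utils::read.csv(path, comment.char = "#")
  if (!all(c("position_mm", "value") %in% names(df)))
    stop("profile CSV must have columns 'position_mm' and 'value'",
         call. = FALSE)
  beam_profile(df$position_mm, df$value, axis = meta$axis %||% "X",
               meta = meta[setdiff(names(meta), "axis")])
}
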