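#' Wavelength grid for an EEM measurement
#'
#' An excitation-emission matrix (EEM) is recorded over a fixed grid of
#' excitation and emission wavelengths shared by every sample in a cube.
#'
#' @param excitation Numeric vector of excitation wavelengths (nm), strictly
#'   increasing.
#' @param emission Numeric vector of emission wavelengths (nm), strictly
#'   increasing.
#'
#' @return An object of class `wavelength_grid` with elements `excitation`
#'   and `emission`.
#' @export
#' @examples
#' g <- wavelength_grid(excitation = c(240, 250, 260),
#'                      emission = seq(300, 400, by = 10))
#' g
wavelength_grid <- function(excitation, emission) {
  check_axis(excitation, "excitation")
  check_axis(emission, "emission")
  structure(
    list(excitation = as.numeric(excitation), emission = as.numeric(emission)),
    class = "wavelength_grid"
  )
}

check_axis <- function(x, name) {
  if (length(x) == 0) {
    stop(name, " axis must be non-empty", call. = FALSE)
  }
  if (!is.numeric(x) || !all(is.finite(x))) {
    stop(name, " axis must be finite numeric", call. = FALSE)
  }
  if (length(x) > 1 && any(diff(x) <= 0)) {
    stop(name, " axis must be strictly increasing", call. = FALSE)
  }
  invisible(x)
}

#' @export
print.wavelength_grid <- function(x, ...) {
  cat(sprintf(
    "<wavelength_grid> excitation: %d points (%.1f-%.1f nm), emission: %d points (%.1f-%.1f nm)\n",
    length(x$excitation), min(x$excitation), max(x$excitation),
    length(x$emission), min(x$emission), max(x$emission)
  ))
  invisible(x)
}

#' Default instrument wavelength grid
#'
#' Emission 300--500 nm in 0.5 nm steps (401 points) and 30 excitation points
#' at 236--265 nm in 1 nm steps. Published acquisition settings for this
#' instrument quote a 235--265 nm excitation range at 1 nm steps (31 points)
#' while the recorded data cubes carry 30 excitation channels; the default
#' grid keeps 30 channels so that default cube shapes match recorded data,
#' dropping the first excitation point.
#'
#' @return A [wavelength_grid()] with 30 excitation and 401 emission points.
#' @export
#' @examples
#' g <- default_grid()
#' length(g$emission)   # 401
#' length(g$excitation) # 30
default_grid <- function() {
  wavelength_grid(
    excitation = seq(236, 265, by = 1),
    emission = seq(300, 500, by = 0.5)
  )
}

valid_roles <- c("calibration", "validation", "test", "blank", "unknown")

#' Construct a single EEM sample
#'
#' @param sample_id Character scalar, unique within a cube.
#' @param intensities Numeric matrix of fluorescence intensities, rows =
#'   emission wavelengths, columns = excitation wavelengths. Negative values
#'   are allowed (detector noise); non-finite values are rejected.
#' @param role One of `"calibration"`, `"validation"`, `"test"`, `"blank"`,
#'   `"unknown"`.
#' @param concentration Analyte concentration in molar units, `NA` for
#'   unknowns, 0 for blanks.
#'
#' @return An object of class `eem_sample`.
#' @export
eem_sample <- function(sample_id, intensities, role = "unknown",
                       concentration = NA_real_) {
  if (!is.character(sample_id) || length(sample_id) != 1 || !nzchar(sample_id)) {
    stop("sample_id must be a non-empty character scalar", call. = FALSE)
  }
  if (!is.matrix(intensities) || !is.numeric(intensities)) {
    stop("intensities must be a numeric matrix (emission x excitation)",
         call. = FALSE)
  }
  if (any(!is.finite(intensities))) {
    stop("non-numeric or non-finite intensity cell in sample '", sample_id, "'",
         call. = FALSE)
  }
  role <- match.arg(role, valid_roles)
  concentration <- as.numeric(concentration)
  if (length(concentration) != 1) {
    stop("concentration must be a single value (or NA)", call. = FALSE)
  }
  if (!is.na(concentration) && (!is.finite(concentration) || concentration < 0)) {
    stop("concentration must be finite and >= 0 when present", call. = FALSE)
  }
  structure(
    list(sample_id = sample_id, intensities = intensities, role = role,
         concentration = concentration),
    class = "eem_sample"
  )
}

#' Construct an EEM cube
#'
#' Stacks EEM samples that share one wavelength grid into a three-way data
#' cube (samples x excitation x emission).
#'
#' @param grid A [wavelength_grid()].
#' @param samples List of [eem_sample()] objects, all with intensity matrices
#'   of dimension `length(grid$emission)` x `length(grid$excitation)` and
#'   unique `sample_id`s.
#'
#' @return An object of class `eem_cube`.
#' @export
#' @examples
#' g <- wavelength_grid(c(240, 250), c(300, 310))
#' s <- eem_sample("a", matrix(1:4, 2, 2), role = "calibration",
#'                 concentration = 1e-7)
#' eem_cube(g, list(s))
eem_cube <- function(grid, samples) {
  if (!inherits(grid, "wavelength_grid")) {
    stop("grid must be a wavelength_grid", call. = FALSE)
  }
  if (!is.list(samples) || length(samples) == 0) {
    stop("cube must contain at least one sample", call. = FALSE)
  }
  n_em <- length(grid$emission)
  n_ex <- length(grid$excitation)
  ids <- character(length(samples))
  for (i in seq_along(samples)) {
    s <- samples[[i]]
    if (!inherits(s, "eem_sample")) {
      stop("samples must be a list of eem_sample objects", call. = FALSE)
    }
    d <- dim(s$intensities)
    if (d[1] != n_em || d[2] != n_ex) {
      stop(sprintf(
        "axis mismatch for sample '%s': intensity matrix is %d x %d but the grid is %d emission x %d excitation",
        s$sample_id, d[1], d[2], n_em, n_ex), call. = FALSE)
    }
    ids[i] <- s$sample_id
  }
  if (anyDuplicated(ids)) {
    stop("duplicate sample_id: ", ids[duplicated(ids)][1], call. = FALSE)
  }
  structure(list(grid = grid, samples = samples), class = "eem_cube")
}

#' @export
print.eem_cube <- function(x, ...) {
  roles <- table(vapply(x$samples, function(s) s$role, character(1)))
  cat(sprintf("<eem_cube> %d samples x %d excitation x %d emission\n",
              length(x$samples), length(x$grid$excitation),
              length(x$grid$emission)))
  cat("  roles:", paste(sprintf("%s=%d", names(roles), roles), collapse = ", "),
      "\n")
  invisible(x)
}

#' Number of samples in a cube
#' @param cube An [eem_cube()].
#' @return Integer count.
#' @export
n_samples <- function(cube) length(cube$samples)

#' Sample metadata of a cube
#'
#' @param cube An [eem_cube()].
#' @return A data.frame with columns `sample_id`, `role`,
#'   `concentration_molar` in cube order.
#' @export
cube_metadata <- function(cube) {
  data.frame(
    sample_id = vapply(cube$samples, function(s) s$sample_id, character(1)),
    role = vapply(cube$samples, function(s) s$role, character(1)),
    concentration_molar = vapply(cube$samples, function(s) s$concentration,
                                 numeric(1)),
    stringsAsFactors = FALSE
  )
}

#' Concentrations of cube samples
#' @param cube An [eem_cube()].
#' @return Numeric vector of molar concentrations (`NA` for unknowns).
#' @export
concentrations <- function(cube) {
  vapply(cube$samples, function(s) s$concentration, numeric(1))
}

# full-precision number formatting so text round-trips are exact
fmt_num <- function(x) {
  out <- formatC(x, digits = 17, format = "g")
  gsub(" ", "", out)
}

detect_sep <- function(line) {
  if (grepl("\t", line)) "\t" else if (grepl(";", line)) ";" else ","
}

read_grid_file <- function(path, sample_id) {
  if (!file.exists(path)) {
    stop("missing grid file for sample '", sample_id, "': ", path,
         call. = FALSE)
  }
  first <- readLines(path, n = 1)
  sep <- detect_sep(first)
  tab <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                           row.names = 1, colClasses = "character",
                           comment.char = "")
  em <- suppressWarnings(as.numeric(rownames(tab)))
  ex <- suppressWarnings(as.numeric(colnames(tab)))
  if (any(is.na(em)) || any(is.na(ex))) {
    stop("non-numeric wavelength labels in grid file ", path, call. = FALSE)
  }
  vals <- suppressWarnings(vapply(tab, as.numeric, numeric(nrow(tab))))
  vals <- matrix(as.numeric(vals), nrow = nrow(tab), ncol = ncol(tab))
  if (any(is.na(vals))) {
    stop("non-numeric intensity cell in grid file ", path, call. = FALSE)
  }
  list(emission = em, excitation = ex, values = vals)
}

#' Read an EEM cube from a manifest of grid files
#'
#' The manifest is delimited text with header
#' `sample_id,grid_file,role,concentration_molar`; `grid_file` paths are
#' resolved relative to the manifest's directory. Each grid file is a
#' delimited table with emission wavelengths as row labels and excitation
#' wavelengths as column labels (comma, semicolon, or tab delimited,
#' auto-detected).
#'
#' @param manifest_path Path to the manifest file.
#' @return A validated [eem_cube()]; sample order follows the manifest.
#' @export
read_eem_cube <- function(manifest_path) {
  if (!file.exists(manifest_path)) {
    stop("missing manifest file: ", manifest_path, call. = FALSE)
  }
  sep <- detect_sep(readLines(manifest_path, n = 1))
  man <- utils::read.table(manifest_path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, colClasses = "character")
  need <- c("sample_id", "grid_file", "role", "concentration_molar")
  if (!all(need %in% names(man))) {
    stop("manifest must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  base <- dirname(manifest_path)
  grid <- NULL
  samples <- vector("list", nrow(man))
  for (i in seq_len(nrow(man))) {
    path <- man$grid_file[i]
    if (!file.exists(path)) path <- file.path(base, man$grid_file[i])
    g <- read_grid_file(path, man$sample_id[i])
    if (is.null(grid)) {
      grid <- wavelength_grid(g$excitation, g$emission)
    } else if (!isTRUE(all.equal(grid$emission, g$emission)) ||
               !isTRUE(all.equal(grid$excitation, g$excitation))) {
      stop(sprintf(
        "axis mismatch: sample '%s' has a %d x %d grid inconsistent with the cube's %d emission x %d excitation axes",
        man$sample_id[i], length(g$emission), length(g$excitation),
        length(grid$emission), length(grid$excitation)), call. = FALSE)
    }
    conc <- man$concentration_molar[i]
    conc <- if (is.na(conc) || !nzchar(trimws(conc))) NA_real_ else {
      v <- suppressWarnings(as.numeric(conc))
      if (is.na(v)) stop("non-numeric concentration for sample '",
                         man$sample_id[i], "'", call. = FALSE)
      v
    }
    samples[[i]] <- eem_sample(man$sample_id[i], g$values,
                               role = man$role[i], concentration = conc)
  }
  eem_cube(grid, samples)
}

#' Write an EEM cube to a directory of grid files plus a manifest
#'
#' Inverse of [read_eem_cube()]: values and wavelength axes round-trip
#' exactly (written at full double precision).
#'
#' @param cube An [eem_cube()].
#' @param out_dir Directory to write into (created if absent).
#' @return The manifest path, invisibly usable with [read_eem_cube()].
#' @export
write_eem_cube <- function(cube, out_dir) {
  if (!inherits(cube, "eem_cube")) stop("cube must be an eem_cube",
                                        call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) {
    stop("cannot create output directory: ", out_dir, call. = FALSE)
  }
  meta <- cube_metadata(cube)
  files <- paste0(gsub("[^A-Za-z0-9_.-]", "_", meta$sample_id), ".tsv")
  for (i in seq_along(cube$samples)) {
    s <- cube$samples[[i]]
    m <- s$intensities
    lines <- c(
      paste(c("em_nm", fmt_num(cube$grid$excitation)), collapse = "\t"),
      vapply(seq_len(nrow(m)), function(r) {
        paste(c(fmt_num(cube$grid$emission[r]), fmt_num(m[r, ])),
              collapse = "\t")
      }, character(1))
    )
    writeLines(lines, file.path(out_dir, files[i]))
  }
  man <- data.frame(
    sample_id = meta$sample_id,
    grid_file = files,
    role = meta$role,
    concentration_molar = ifelse(is.na(meta$concentration_molar), "",
                                 fmt_num(meta$concentration_molar)),
    stringsAsFactors = FALSE
  )
  manifest_path <- file.path(out_dir, "manifest.csv")
  utils::write.table(man, manifest_path, sep = ",", row.names = FALSE,
                     quote = FALSE)
  invisible(manifest_path)
}

#' Long-format export of a cube
#'
#' @param cube An [eem_cube()].
#' @return A data.frame with columns `sample_id`, `ex_nm`, `em_nm`,
#'   `intensity`, one row per measured point.
#' @export
cube_to_long <- function(cube) {
  n_em <- length(cube$grid$emission)
  n_ex <- length(cube$grid$excitation)
  do.call(rbind, lapply(cube$samples, function(s) {
    data.frame(
      sample_id = s$sample_id,
      ex_nm = rep(cube$grid$excitation, each = n_em),
      em_nm = rep(cube$grid$emission, times = n_ex),
      intensity = as.vector(s$intensities),
      stringsAsFactors = FALSE
    )
  }))
}
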