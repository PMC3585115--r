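# Tabular outputs are tab-delimited, one header line, with `#`-prefixed
# metadata lines so files stay diff-able and language neutral.

write_tsv_meta <- function(x, path, meta = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  for (m in meta) writeLines(paste0("# ", m), con)
  utils::write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv_plain <- function(path) {
  readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                  progress = FALSE)
}

#' Read and write PWM count tables
#'
#' The count-table format holds one matrix per factor, introduced by a
#' `>tf` header line, followed by four labeled base rows (A, C, G, T) of
#' whitespace-separated counts — the number of observed bases at each
#' position of the aligned sites. A file may hold one matrix or many.
#'
#' @param path File path.
#' @param background,pseudocount Passed to [build_pwm()].
#' @return `read_pwm_counts()`: a named list of [build_pwm()] objects.
#' @export
read_pwm_counts <- function(path, background = rep(0.25, 4),
                            pseudocount = 1) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  heads <- which(startsWith(lines, ">"))
  if (length(heads) == 0) {
    stop("no '>tf' header found in PWM count file ", path, call. = FALSE)
  }
  ends <- c(heads[-1] - 1L, length(lines))
  pwms <- lapply(seq_along(heads), function(k) {
    tf <- sub("^>\\s*", "", lines[heads[k]])
    body <- lines[(heads[k] + 1L):ends[k]]
    rows <- strsplit(body, "\\s+")
    bases <- toupper(vapply(rows, `[`, character(1), 1))
    if (!setequal(bases, DNA_BASES)) {
      stop("PWM block for ", tf, " must have rows labeled A, C, G, T",
           call. = FALSE)
    }
    counts <- do.call(rbind, lapply(rows, function(r) as.numeric(r[-1])))
    rownames(counts) <- bases
    build_pwm(counts, tf = tf, background = background,
              pseudocount = pseudocount)
  })
  stats::setNames(pwms, vapply(pwms, function(p) p$tf, character(1)))
}

#' @rdname read_pwm_counts
#' @param counts Named list of count matrices (width x 4 or 4 x width),
#'   written verbatim.
#' @return `write_pwm_counts()`: the path, invisibly.
#' @export
write_pwm_counts <- function(counts, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (tf in names(counts)) {
    m <- as_counts_matrix(counts[[tf]])
    writeLines(paste0(">", tf), con)
    for (b in DNA_BASES) {
      writeLines(paste(c(b, format(m[, b], trim = TRUE)), collapse = "\t"),
                 con)
    }
  }
  invisible(path)
}

#' Read construct sequences from FASTA
#'
#' Record ids are construct ids; TSS positions and targeting flags come
#' from the run configuration, not from the FASTA.
#'
#' @param path FASTA file path.
#' @return Named character vector of sequences.
#' @export
read_fasta_sequences <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), sub("\\s.*", "", names(x)))
}

#' @rdname read_fasta_sequences
#' @param seqs Named character vector of sequences.
#' @export
write_fasta_sequences <- function(seqs, path) {
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(seqs), filepath = path)
  invisible(path)
}

#' Read and write concentration / expression profile tables
#'
#' Tab-delimited, one row per anterior-posterior position: a `position`
#' column (% egg length) plus one column per factor (or per quantity, e.g.
#' `rate` or `observed`).
#'
#' @param x Profile tibble.
#' @param path File path.
#' @param meta Character vector of metadata lines.
#' @export
write_profile_table <- function(x, path, meta = character()) {
  write_tsv_meta(x, path, meta)
}

#' @rdname write_profile_table
#' @export
read_profile_table <- function(path) {
  read_tsv_plain(path)
}

#' Write and read a site table
#'
#' BED-flavored columns (`construct`, `start`, `end`, `tf`, `score`,
#' `strand`, plus affinity and footprint columns), 0-based half-open.
#'
#' @param sites Site tibble.
#' @param construct Construct id recorded in the first column.
#' @param path File path.
#' @export
write_site_table <- function(sites, path, construct = "construct") {
  out <- dplyr::mutate(sites, construct = construct, .before = 1)
  write_tsv_meta(out, path)
}

#' @rdname write_site_table
#' @export
read_site_table <- function(path) {
  read_tsv_plain(path)
}

#' Serialize and restore a parameter table
#'
#' Flat key-value text: one row per parameter with its qualifier (TF or
#' construct), value, bounds, free flag, and search scale.
#'
#' @param params Parameter tibble.
#' @param path File path.
#' @export
write_params <- function(params, path) {
  write_tsv_meta(params, path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  p <- read_tsv_plain(path)
  p$tf <- as.character(p$tf)
  p$free <- as.logical(p$free)
  check_params(p)
  class(p) <- c("model_params", class(tibble::tibble()))
  p
}

#' Write and read a training set directory
#'
#' On disk a training set is a directory holding a manifest
#' (`constructs.tsv`: construct id, TSS offset, targeted flag), the
#' construct sequences (`constructs.fa`), the shared concentration
#' profiles (`tf_profiles.tsv`), one observed-expression table per
#' construct (`obs_<id>.tsv`), and optionally the generating parameters
#' (`true_params.tsv`).
#'
#' @param data A `training_set`.
#' @param dir Directory path (created if needed).
#' @export
write_training_set <- function(data, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_tsv_meta(data$constructs[, c("construct", "tss", "targeted")],
                 file.path(dir, "constructs.tsv"))
  write_fasta_sequences(
    stats::setNames(data$constructs$seq, data$constructs$construct),
    file.path(dir, "constructs.fa"))
  write_profile_table(data$profiles, file.path(dir, "tf_profiles.tsv"))
  for (id in data$constructs$construct) {
    rows <- data$observations[data$observations$construct == id,
                              c("position", "observed")]
    write_profile_table(rows, file.path(dir, paste0("obs_", id, ".tsv")))
  }
  if (!is.null(data$true_params)) {
    write_params(data$true_params, file.path(dir, "true_params.tsv"))
  }
  invisible(dir)
}

#' @rdname write_training_set
#' @export
read_training_set <- function(dir) {
  manifest <- read_tsv_plain(file.path(dir, "constructs.tsv"))
  seqs <- read_fasta_sequences(file.path(dir, "constructs.fa"))
  manifest$seq <- unname(seqs[manifest$construct])
  profiles <- read_profile_table(file.path(dir, "tf_profiles.tsv"))
  obs <- purrr::map_dfr(manifest$construct, function(id) {
    rows <- read_profile_table(file.path(dir, paste0("obs_", id, ".tsv")))
    dplyr::mutate(rows, construct = id, .before = 1)
  })
  tp_path <- file.path(dir, "true_params.tsv")
  structure(
    list(constructs = manifest[, c("construct", "seq", "tss", "targeted")],
         profiles = profiles, observations = obs,
         true_params = if (file.exists(tp_path)) read_params(tp_path),
         noise_sd = NA_real_, seed = NA_integer_),
    class = "training_set")
}

#' Load a run configuration
#'
#' Reads a YAML run configuration declaring input paths (sequences, PWM
#' counts, profiles, observations), the model configuration overrides (TF
#' roster, constants), and run options (seed, optimizer, budget,
#' knockouts). All referenced paths are checked at load and every factor
#' referenced by the roster must have a PWM and a profile column.
#'
#' @param path YAML file path.
#' @return A validated list of class `run_config` with elements `paths`,
#'   `model` (a `model_config`), `params`, and `options`.
#' @export
load_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  resolve <- function(p) {
    if (is.null(p)) return(NULL)
    if (!file.exists(p) && file.exists(file.path(base, p))) {
      p <- file.path(base, p)
    }
    if (!file.exists(p)) stop("config references missing path: ", p,
                              call. = FALSE)
    p
  }
  paths <- lapply(raw$paths %||% list(), resolve)
  model <- default_model_config()
  for (nm in intersect(names(raw$model %||% list()),
                       c("coop_range_bp", "quench_r_full", "quench_r_zero",
                         "coact_offset_bp", "enumeration_cap",
                         "ap_range", "n_positions"))) {
    model[[nm]] <- raw$model[[nm]]
  }
  params <- if (!is.null(paths$params)) {
    read_params(paths$params)
  } else {
    default_params(model)
  }
  pwms <- if (!is.null(paths$pwms)) read_pwm_counts(paths$pwms)
  if (!is.null(pwms)) {
    missing <- setdiff(model$tfs$tf, names(pwms))
    if (length(missing)) {
      stop("config error: no PWM for TF ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
  }
  if (!is.null(paths$profiles)) {
    prof <- read_profile_table(paths$profiles)
    missing <- setdiff(model$tfs$tf, names(prof))
    if (length(missing)) {
      stop("config error: no profile column for TF ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
  }
  opts <- raw$options %||% list()
  opts$seed <- opts$seed %||% 1L
  opts$optimizer <- opts$optimizer %||% "generic_sa"
  opts$budget <- opts$budget %||% 2e5
  structure(list(paths = paths, model = model, params = params,
                 options = opts, source = normalizePath(path)),
            class = "run_config")
}

#' Write a provenance log for a run
#'
#' Records the configuration digest, seed, package version and timestamp
#' so a run can be reproduced from its log alone.
#'
#' @param path Output file.
#' @param config_path Path of the run configuration used.
#' @param seed Seed used.
#' @param extra Named list of additional fields.
#' @export
write_provenance <- function(path, config_path = NA_character_, seed = NA,
                             extra = list()) {
  digest <- if (!is.na(config_path) && file.exists(config_path)) {
    # content hash without external dependencies: sum of a rolling
    # polynomial over the bytes, printed in hex
    bytes <- as.integer(charToRaw(paste(readLines(config_path,
                                                  warn = FALSE),
                                        collapse = "\n")))
    h <- 0
    for (b in bytes) h <- (h * 31 + b) %% 2^31
    sprintf("%08x", h)
  } else NA_character_
  fields <- c(
    list(package = "thermotrx",
         version = as.character(utils::packageVersion("thermotrx")),
         timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
         config = config_path, config_digest = digest, seed = seed),
    extra)
  writeLines(paste0(names(fields), "\t",
                    vapply(fields, function(x) paste(x, collapse = ","),
                           character(1))),
              path)
  invisible(path)
}
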