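## File formats: the site-group FASTA dialect, profile/posterior TSVs, and
## run manifests.
##
## Site-group FASTA dialect: FASTA records with headers
##   >site_id|species|chrom:start-end|strand
## Records sharing a site_id are consecutive and form one group; the first
## record of a group is the reference species.  Coordinates are 0-based
## half-open on the reference; strand is + or -; reverse-strand instances
## are stored already reverse-complemented to motif orientation.  Sequences
## are gapless, uppercase ACGT, equal length within a group.

#' Read site groups from a site-group FASTA file
#'
#' Parses and validates the dialect described under *Details*.  Groups
#' containing `N` or other non-ACGT characters are dropped with a warning;
#' structural problems (length mismatch within a group, duplicate species)
#' are fatal under `strict = TRUE` and skip the offending group otherwise.
#'
#' @param path File path.
#' @param strict Fatal (`TRUE`, default) or skip-with-warning (`FALSE`)
#'   handling of malformed groups.
#' @return A site-group tibble: `site_id`, `species`, `chrom`, `start`,
#'   `end`, `strand`, `seq`.
#' @export
read_sitegroups <- function(path, strict = TRUE) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  hdr_idx <- grep("^>", lines)
  if (length(hdr_idx) == 0L) abort("No FASTA headers found.")
  rx <- "^>([^|]+)\\|([^|]+)\\|([^:|]+):([0-9]+)-([0-9]+)\\|([+-])$"
  recs <- vector("list", length(hdr_idx))
  bounds <- c(hdr_idx, length(lines) + 1L)
  for (i in seq_along(hdr_idx)) {
    h <- lines[hdr_idx[i]]
    m <- regmatches(h, regexec(rx, h))[[1]]
    if (length(m) == 0L) {
      msg <- sprintf("Malformed header at line %d: %s", hdr_idx[i], h)
      if (strict) abort(msg) else { warn(msg); recs[i] <- list(NULL); next }
    }
    body <- if (hdr_idx[i] + 1L > bounds[i + 1L] - 1L) character(0)
            else lines[(hdr_idx[i] + 1L):(bounds[i + 1L] - 1L)]
    seq <- toupper(paste(body[!grepl("^>", body)], collapse = ""))
    if (!nzchar(seq)) {
      msg <- sprintf("Empty sequence for header at line %d.", hdr_idx[i])
      if (strict) abort(msg) else { warn(msg); recs[i] <- list(NULL); next }
    }
    recs[[i]] <- tibble::tibble(
      site_id = m[2], species = m[3], chrom = m[4],
      start = as.integer(m[5]), end = as.integer(m[6]), strand = m[7],
      seq = seq, line = hdr_idx[i]
    )
  }
  out <- dplyr::bind_rows(recs)
  if (nrow(out) == 0L) abort("No valid records parsed.")

  drop_group <- function(df, why, fatal) {
    msg <- sprintf("Site group '%s' (line %d): %s", df$site_id[1], df$line[1], why)
    if (fatal) abort(msg)
    warn(paste(msg, "— group skipped."))
    NULL
  }
  n_dropped_n <- 0L
  parts <- split(out, factor(out$site_id, levels = unique(out$site_id)))
  kept <- lapply(parts, function(df) {
    if (any(grepl("[^ACGT]", df$seq))) {
      n_dropped_n <<- n_dropped_n + 1L
      warn(sprintf("Site group '%s' contains non-ACGT characters — dropped.", df$site_id[1]))
      return(NULL)
    }
    if (anyDuplicated(df$species)) return(drop_group(df, "duplicate species", strict))
    if (length(unique(nchar(df$seq))) != 1L) {
      return(drop_group(df, "sequences of unequal length", strict))
    }
    df
  })
  res <- dplyr::bind_rows(kept)
  if (nrow(res) == 0L) abort("All site groups were invalid.")
  dplyr::select(res, -"line")
}

#' Write site groups in the site-group FASTA dialect
#'
#' @param groups Site-group tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sitegroups <- function(groups, path) {
  lines <- unlist(purrr::pmap(
    groups[, c("site_id", "species", "chrom", "start", "end", "strand", "seq")],
    function(site_id, species, chrom, start, end, strand, seq) {
      c(sprintf(">%s|%s|%s:%d-%d|%s", site_id, species, chrom, start, end, strand),
        seq)
    }))
  writeLines(lines, path)
  invisible(path)
}

#' Write a profile (PWM/PSSV) as TSV
#'
#' Tab-separated `pos A C G T` with 6-decimal probabilities.  Positions are
#' written 0-based (file dialect); the in-R representation is 1-based.
#'
#' @param profile A profile.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_profile_tsv <- function(profile, path) {
  m <- profile_matrix(profile)
  lines <- c("pos\tA\tC\tG\tT",
             vapply(seq_len(nrow(m)), function(i) {
               paste(c(i - 1L, sprintf("%.6f", m[i, ])), collapse = "\t")
             }, ""))
  writeLines(lines, path)
  invisible(path)
}

#' Read a profile TSV written by [write_profile_tsv()]
#'
#' Rows are renormalized to counteract 6-decimal rounding.
#'
#' @param path File path.
#' @param type Class of the returned profile.
#' @return A profile tibble.
#' @export
read_profile_tsv <- function(path, type = c("pssv", "pwm")) {
  type <- match.arg(type)
  df <- utils::read.delim(path, check.names = FALSE)
  if (!all(c("pos", NUC) %in% names(df))) abort("Not a profile TSV (need pos, A, C, G, T).")
  m <- normalize_rows(as.matrix(df[, NUC]))
  new_profile(m, positions = df$pos + 1L, type = type)
}

#' Write ancestral posteriors as TSV
#'
#' Tab-separated `site_id pos A C G T`, positions 0-based on disk.
#'
#' @param posterior Tibble from [ancestral_posterior()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_posterior_tsv <- function(posterior, path) {
  lines <- c("site_id\tpos\tA\tC\tG\tT",
             purrr::pmap_chr(posterior, function(site_id, position, A, C, G, T) {
               paste(c(site_id, position - 1L, sprintf("%.6f", c(A, C, G, T))),
                     collapse = "\t")
             }))
  writeLines(lines, path)
  invisible(path)
}

#' Write a run manifest
#'
#' Records everything needed to reproduce a pipeline stage byte-for-byte:
#' parameters, seed, package version, and any reported log-likelihoods.
#'
#' @param path Output path (JSON).
#' @param ... Named fields to record.
#' @return `path`, invisibly.
#' @export
write_run_manifest <- function(path, ...) {
  manifest <- c(
    list(package = "pssver",
         version = as.character(utils::packageVersion("pssver")),
         r_version = as.character(getRversion()),
         timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    list(...)
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
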