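SAMPLE_SHEET_COLUMNS <- c(
  "sample_id", "group", "sex", "cohort", "chip", "batch",
  "bsce_c1", "bsce_c2", "age_at_draw", "age_at_diagnosis",
  "duration_t1d", "time_to_event", "event"
)

MANIFEST_COLUMNS <- c(
  "probe_id", "chromosome", "position", "gene_symbol",
  "tss_distance", "cgi_member"
)

#' Read a sample sheet
#'
#' Reads the per-sample phenotype and technical-covariate table (CSV).
#' Required columns: `sample_id`, `group` (`case`/`control`), `sex`,
#' `cohort`, `chip`, `batch`, `bsce_c1`, `bsce_c2` (bisulphite conversion
#' efficiency metrics), `age_at_draw`, `age_at_diagnosis`, `duration_t1d`,
#' `time_to_event`, `event`. The survival encoding is: cases have
#' `event = 1` and `time_to_event` equal to years from diabetes diagnosis to
#' nephropathy onset; controls have `event = 0` censored at their diabetes
#' duration (`time_to_event == duration_t1d`). Unknown extra columns are
#' accepted and dropped with a warning.
#'
#' @param path Path to the CSV file.
#' @return A `data.frame`, one row per sample, with `group`, `sex`,
#'   `cohort`, `chip` and `batch` as factors.
#' @export
read_sample_sheet <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(SAMPLE_SHEET_COLUMNS, names(df))
  if (length(missing_cols) > 0)
    stop("sample sheet is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  extra <- setdiff(names(df), SAMPLE_SHEET_COLUMNS)
  if (length(extra) > 0) {
    warning("ignoring extra sample-sheet column(s): ",
            paste(extra, collapse = ", "))
    df <- df[SAMPLE_SHEET_COLUMNS]
  }
  validate_samples(df)
}

validate_samples <- function(df) {
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample_id: ", df$sample_id[duplicated(df$sample_id)][1L])
  if (!all(df$event %in% c(0L, 1L))) stop("event must be 0 or 1")
  if (any(df$time_to_event <= 0)) stop("time_to_event must be positive")
  if (!all(df$group %in% c("case", "control")))
    stop("group must be 'case' or 'control'")
  bad_case <- df$group == "case" & df$event != 1L
  if (any(bad_case))
    stop("case with event = 0: ", df$sample_id[bad_case][1L])
  bad_ctrl <- df$group == "control" &
    (df$event != 0L | abs(df$time_to_event - df$duration_t1d) > 1e-6)
  if (any(bad_ctrl))
    stop("control must be censored at its T1D duration ",
         "(event = 0, time_to_event = duration_t1d): ",
         df$sample_id[bad_ctrl][1L])
  if (any(df$age_at_draw < df$age_at_diagnosis - 1e-6))
    stop("age_at_draw must be >= age_at_diagnosis")
  for (col in c("group", "sex", "cohort", "chip", "batch"))
    df[[col]] <- factor(df[[col]])
  df
}

#' Read a probe manifest
#'
#' Reads the probe annotation table (CSV): `probe_id`, `chromosome`
#' (without a `chr` prefix), `position` (1-based bp), `gene_symbol`,
#' `tss_distance` (signed bp to the transcription start site) and
#' `cgi_member` (CpG-island membership flag).
#'
#' @param path Path to the CSV file.
#' @return A `data.frame`, one row per probe.
#' @export
read_probe_manifest <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE,
                 colClasses = c(chromosome = "character"))
  missing_cols <- setdiff(MANIFEST_COLUMNS, names(df))
  if (length(missing_cols) > 0)
    stop("probe manifest is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  if (anyDuplicated(df$probe_id))
    stop("duplicate probe_id in manifest: ",
         df$probe_id[duplicated(df$probe_id)][1L])
  if (any(df$position < 1)) stop("position must be >= 1")
  df$cgi_member <- as.logical(df$cgi_member)
  df
}

#' Write an EWAS result table
#'
#' Writes per-CpG Cox results as a TSV with the columns
#' `probe_id`, `gene`, `location` (`chromosome:position`), `coef`,
#' `exp_coef`, `se_coef`, `z`, `p`, `q`. Coefficients, hazard ratios,
#' standard errors, z and q are rounded to `digits` decimals; p-values are
#' printed in scientific notation.
#'
#' @param ewas An [run_ewas()] result (or any data frame with columns
#'   `probe_id`, `coef`, `se`, `z`, `p`, `q`).
#' @param path Output path.
#' @param manifest Optional probe manifest used to fill `gene` and
#'   `location`; left as `NA` when absent.
#' @param digits Decimals for fixed-point columns (default 3).
#' @export
write_ewas_table <- function(ewas, path, manifest = NULL, digits = 3) {
  tab <- as.data.frame(ewas)
  gene <- rep(NA_character_, nrow(tab))
  location <- rep(NA_character_, nrow(tab))
  if (!is.null(manifest)) {
    i <- match(tab$probe_id, manifest$probe_id)
    gene <- manifest$gene_symbol[i]
    location <- ifelse(is.na(i), NA_character_,
                       paste0(manifest$chromosome[i], ":", manifest$position[i]))
  }
  fmt <- function(x) formatC(round(x, digits), format = "f", digits = digits)
  out <- data.frame(
    probe_id = tab$probe_id,
    gene = gene,
    location = location,
    coef = fmt(tab$coef),
    exp_coef = fmt(exp(tab$coef)),
    se_coef = fmt(tab$se),
    z = fmt(tab$z),
    p = formatC(tab$p, format = "e", digits = 3),
    q = fmt(tab$q),
    stringsAsFactors = FALSE
  )
  con <- tryCatch(file(path, "w"), error = function(e)
    stop("cannot open for writing: ", path))
  on.exit(close(con))
  write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read back an EWAS result table written by [write_ewas_table()]
#'
#' @param path Path to the TSV file.
#' @return A `data.frame` with numeric `coef`, `exp_coef`, `se_coef`, `z`,
#'   `p`, `q` columns.
#' @export
read_ewas_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  read.delim(path, sep = "\t", stringsAsFactors = FALSE,
             colClasses = c(probe_id = "character"))
}
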