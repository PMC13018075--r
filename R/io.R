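# NONMEM-dialect dataset I/O, deterministic seed streams, and run manifests.

NM_COLS <- c("ID", "TIME", "AMT", "DV", "EVID", "MDV", "CMT", "WT", "AGE", "SEX")

# Compartment codes used throughout: 1 depot (doses), 2 central (PK
# observations), 3 IGF-1, 4 growth velocity.
CMT_DEPOT <- 1L
CMT_PK <- 2L
CMT_IGF1 <- 3L
CMT_GV <- 4L

cmt_to_kind <- function(cmt) {
  c("depot", "pk", "igf1", "gv")[cmt]
}

validate_obs_table <- function(tab) {
  need <- c("ID", "TIME", "AMT", "DV", "EVID")
  missing <- setdiff(need, names(tab))
  if (length(missing) > 0)
    stop("missing required columns: ", paste(missing, collapse = ", "))
  if (!"MDV" %in% names(tab))
    tab$MDV <- ifelse(tab$EVID != 0 | is.na(tab$DV), 1L, 0L)
  bad <- which(tab$EVID == 1 & !is.na(tab$DV))
  if (length(bad) > 0)
    stop("dose rows (EVID=1) must have missing DV; offending rows: ",
         paste(utils::head(bad, 5), collapse = ", "))
  for (id in unique(tab$ID)) {
    tt <- tab$TIME[tab$ID == id]
    if (is.unsorted(tt))
      stop("non-monotone TIME within subject ", id, "; first offending row: ",
           which(tab$ID == id)[which(diff(tt) < 0)[1] + 1])
  }
  tab
}

#' Read / write NONMEM-style observation tables
#'
#' Comma-separated tables with columns ID, TIME, AMT, DV, EVID, MDV, CMT,
#' WT, AGE, SEX. Missing DV is written as `.` (dose rows always have
#' missing DV); `MDV` is inferred when absent. `read_nonmem_csv` validates
#' the dialect and errors with row numbers on violations; the pair
#' round-trips tables exactly.
#'
#' @param path File path.
#' @return `read_nonmem_csv`: a validated data.frame of class `obs_table`.
#' @export
read_nonmem_csv <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  if (nrow(raw) == 0) {
    tab <- as.data.frame(sapply(names(raw), function(x) numeric(0),
                                simplify = FALSE))
  } else {
    tab <- raw
    for (nm in names(tab)) {
      v <- tab[[nm]]
      v[v == "."] <- NA
      tab[[nm]] <- if (nm == "SEX") v else as.numeric(v)
    }
  }
  tab <- validate_obs_table(tab)
  structure(tab, class = c("obs_table", "data.frame"))
}

#' @rdname read_nonmem_csv
#' @param tab Observation table (data.frame with the dialect columns).
#' @export
write_nonmem_csv <- function(tab, path) {
  validate_obs_table(as.data.frame(tab))
  out <- as.data.frame(tab)
  for (nm in names(out)) {
    v <- out[[nm]]
    if (is.numeric(v)) v <- format(v, digits = 17, trim = TRUE, scientific = FALSE)
    v[is.na(out[[nm]])] <- "."
    out[[nm]] <- v
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Deterministic child seed from a master seed and stream name
#'
#' All randomness in the package flows from one master seed through named
#' streams (e.g. `"cohort"`, `"residual"`, `"replicate"`), so that stages
#' can be re-run independently and reruns are bit-reproducible.
#'
#' @param master Master seed (integer).
#' @param name Stream name.
#' @param index Optional stream index (e.g. replicate number).
#' @return An integer seed in `[1, 2^31 - 2]`.
#' @export
seed_stream <- function(master, name, index = 0L) {
  h <- 0
  for (ch in utf8ToInt(name)) h <- (h * 131 + ch) %% 2147480009
  s <- ((master %% 2147480009) * 48271 + h * 69621 + index * 16807) %% 2147483646
  as.integer(s + 1)
}

#' Write / read a run manifest
#'
#' A JSON snapshot of the configuration and master seed that fully
#' determines a simulation rerun.
#'
#' @param config A [sim_config()] (or any serialisable list).
#' @param outputs Named list or character vector of output paths.
#' @param path Manifest path (JSON).
#' @return The manifest list, invisibly for write.
#' @export
write_manifest <- function(config, outputs, path) {
  man <- list(
    package = "pegsim",
    version = as.character(utils::packageVersion("pegsim")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = unclass_deep(config),
    outputs = as.list(outputs)
  )
  jsonlite::write_json(man, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(man)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

unclass_deep <- function(x) {
  if (is.list(x)) {
    x <- unclass(x)
    lapply(x, unclass_deep)
  } else x
}
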