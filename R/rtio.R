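# Plain structured-text fixture dialect for treatment cases.
#
# A case is a pair of files mirroring the RT Plan / RT Structure Set split:
#   <stem>.plan.txt    needles: tip control point + dwell positions/times
#   <stem>.struct.txt  structures: stacked transverse contour polygons
#
# Both are line-oriented, whitespace-separated, '#' comments allowed.
# Coordinates in mm (DICOM patient system), times in seconds.

FIXTURE_MAGIC_PLAN <- "BRACHYROBUST-PLAN"
FIXTURE_MAGIC_STRUCT <- "BRACHYROBUST-STRUCT"

#' Default structure-name alias table
#'
#' Clinical structure naming varies; loading matches names case-insensitively
#' against these aliases.
#' @return named list of character vectors.
#' @export
default_structure_aliases <- function() {
  list(prostate = c("prostate", "ctv", "target", "ctv_prostate"),
       urethra = c("urethra", "urethra_surrogate"),
       rectum = c("rectum", "rectal_wall", "anorectum"))
}

fmt_num <- function(x) sprintf("%.10g", x)

strip_comments <- function(lines) {
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines[nzchar(lines)]
}

#' Load a treatment case from plan and structure files
#'
#' Reads the fixture dialect (see the package README for the schema) and
#' builds the in-memory case model.  DICOM-RT input is not supported by this
#' build; export DICOM plans to the fixture dialect first.
#'
#' @param plan_path path to the plan file (needles, dwell positions/times,
#'   prescription).
#' @param struct_path path to the structure file (contour polygons).
#' @param aliases structure-name alias table, see
#'   [default_structure_aliases()].
#' @param constraints constraint table attached to the case.
#' @return a [case_model()].
#' @export
load_case <- function(plan_path, struct_path,
                      aliases = default_structure_aliases(),
                      constraints = default_constraints()) {
  if (!file.exists(plan_path)) stop("load_case: plan file not found: ", plan_path)
  if (!file.exists(struct_path)) stop("load_case: structure file not found: ", struct_path)
  plan_lines <- strip_comments(readLines(plan_path, warn = FALSE))
  if (length(plan_lines) == 0L || !startsWith(plan_lines[1], FIXTURE_MAGIC_PLAN)) {
    if (is_dicom_file(plan_path))
      stop("load_case: DICOM-RT input is not supported by this build; ",
           "convert the plan to the fixture dialect")
    stop("load_case: not a fixture plan file (missing ", FIXTURE_MAGIC_PLAN,
         " header): ", plan_path)
  }
  prescription <- 16
  positions <- list(); times <- list(); tips <- list()
  cur <- 0L
  for (ln in plan_lines[-1]) {
    tok <- strsplit(ln, "[[:space:]]+")[[1]]
    key <- toupper(tok[1])
    if (key == "PRESCRIPTION_GY") {
      prescription <- as.numeric(tok[2])
    } else if (key == "NEEDLE") {
      cur <- as.integer(tok[2])
      if (toupper(tok[3]) != "TIP")
        stop("load_case: NEEDLE line must carry the TIP control point: ", ln)
      tips[[cur]] <- as.numeric(tok[4:6])
      positions[[cur]] <- matrix(numeric(0), 0, 3)
      times[[cur]] <- numeric(0)
    } else if (key == "DWELL") {
      if (cur == 0L) stop("load_case: DWELL line before any NEEDLE: ", ln)
      positions[[cur]] <- rbind(positions[[cur]], as.numeric(tok[2:4]))
      times[[cur]] <- c(times[[cur]], as.numeric(tok[5]))
    } else {
      stop("load_case: unrecognised plan line: ", ln)
    }
  }
  if (length(positions) == 0L || n_dwells_raw(positions) == 0L)
    stop("load_case: plan contains zero dwells")
  dwells <- dwell_set(positions, times, tips)

  contours <- read_structures(struct_path, aliases)
  case_model(dwells, contours, prescription = prescription,
             constraints = constraints)
}

n_dwells_raw <- function(positions) sum(vapply(positions, nrow, integer(1)))

is_dicom_file <- function(path) {
  con <- file(path, "rb"); on.exit(close(con))
  hdr <- readBin(con, "raw", 132)
  length(hdr) == 132 && rawToChar(hdr[129:132]) == "DICM"
}

read_structures <- function(struct_path, aliases) {
  lines <- strip_comments(readLines(struct_path, warn = FALSE))
  if (length(lines) == 0L || !startsWith(lines[1], FIXTURE_MAGIC_STRUCT))
    stop("read_structures: not a fixture structure file (missing ",
         FIXTURE_MAGIC_STRUCT, " header): ", struct_path)
  raw <- list()   # name -> list(slice_width, slices)
  cur_name <- NULL; cur_z <- NULL; cur_vs <- NULL
  flush_slice <- function() {
    if (!is.null(cur_z)) {
      sl <- cbind(cur_vs, rep(cur_z, nrow(cur_vs)))
      raw[[cur_name]]$slices[[length(raw[[cur_name]]$slices) + 1L]] <<- sl
    }
    cur_z <<- NULL; cur_vs <<- NULL
  }
  for (ln in lines[-1]) {
    tok <- strsplit(ln, "[[:space:]]+")[[1]]
    key <- toupper(tok[1])
    if (key == "STRUCTURE") {
      flush_slice()
      cur_name <- tok[2]
      if (toupper(tok[3]) != "SLICE_WIDTH")
        stop("read_structures: STRUCTURE line must carry SLICE_WIDTH: ", ln)
      raw[[cur_name]] <- list(slice_width = as.numeric(tok[4]), slices = list())
    } else if (key == "SLICE") {
      flush_slice()
      if (is.null(cur_name)) stop("read_structures: SLICE before any STRUCTURE")
      cur_z <- as.numeric(tok[2])
      cur_vs <- matrix(numeric(0), 0, 2)
    } else if (key == "V") {
      if (is.null(cur_z)) stop("read_structures: vertex line outside a SLICE")
      cur_vs <- rbind(cur_vs, as.numeric(tok[2:3]))
    } else {
      stop("read_structures: unrecognised structure line: ", ln)
    }
  }
  flush_slice()

  found <- list()
  avail <- names(raw)
  for (canon in STRUCTURE_NAMES) {
    hit <- avail[tolower(avail) %in% tolower(aliases[[canon]])]
    if (length(hit) == 0L)
      stop(sprintf(
        "read_structures: structure '%s' not found; available structures: %s",
        canon, paste(avail, collapse = ", ")))
    r <- raw[[hit[1]]]
    found[[canon]] <- structure_contours(r$slices, r$slice_width, name = canon)
  }
  contour_set(found$prostate, found$urethra, found$rectum)
}

#' Write a treatment case to a file pair
#'
#' @param case a [case_model()].
#' @param out_stem output path stem; `<stem>.plan.txt` and
#'   `<stem>.struct.txt` are written.
#' @param dialect only `"fixture"` is supported by this build.
#' @return character vector of the two file paths, invisibly.
#' @export
write_case <- function(case, out_stem, dialect = c("fixture", "dicom")) {
  dialect <- match.arg(dialect)
  if (dialect == "dicom")
    stop("write_case: DICOM-RT output is not supported by this build")
  stopifnot(inherits(case, "case_model"))
  plan_path <- paste0(out_stem, ".plan.txt")
  struct_path <- paste0(out_stem, ".struct.txt")

  pl <- c(paste(FIXTURE_MAGIC_PLAN, "1"),
          paste("PRESCRIPTION_GY", fmt_num(case$prescription)))
  for (i in seq_len(n_needles(case$dwells))) {
    tip <- case$dwells$tips[[i]]
    pl <- c(pl, paste("NEEDLE", i, "TIP", fmt_num(tip[1]), fmt_num(tip[2]),
                      fmt_num(tip[3])))
    P <- case$dwells$positions[[i]]; tt <- case$dwells$times[[i]]
    for (j in seq_len(nrow(P)))
      pl <- c(pl, paste("DWELL", fmt_num(P[j, 1]), fmt_num(P[j, 2]),
                        fmt_num(P[j, 3]), fmt_num(tt[j])))
  }
  ok <- tryCatch({ writeLines(pl, plan_path); TRUE },
                 error = function(e) stop("write_case: cannot write ", plan_path,
                                          ": ", conditionMessage(e)))

  st <- paste(FIXTURE_MAGIC_STRUCT, "1")
  for (nm in STRUCTURE_NAMES) {
    s <- case$contours[[nm]]
    st <- c(st, paste("STRUCTURE", nm, "SLICE_WIDTH", fmt_num(s$slice_width)))
    for (sl in s$slices) {
      st <- c(st, paste("SLICE", fmt_num(sl[1, 3])))
      st <- c(st, paste("V", fmt_num(sl[, 1]), fmt_num(sl[, 2])))
    }
  }
  tryCatch(writeLines(st, struct_path),
           error = function(e) stop("write_case: cannot write ", struct_path,
                                    ": ", conditionMessage(e)))
  invisible(c(plan = plan_path, structures = struct_path))
}
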