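# Delimited-file plumbing and the command-line entry point. All formats are
# plain text: a '# key=value' header block followed by a tab-separated
# table. Times are seconds; sample indexing is 0-based in time.

readHeader <- function(lines) {
  hdr <- grep("^#", lines, value = TRUE)
  kv <- sub("^#\\s*", "", hdr)
  kv <- kv[grepl("=", kv)]
  keys <- sub("=.*$", "", kv)
  vals <- sub("^[^=]*=", "", kv)
  setNames(as.list(vals), keys)
}

#' Write / read a dyad recording as a delimited file
#'
#' The format is a `# key=value` header (`fs`, `dyad_id`, `channels`)
#' followed by a tab-separated table with a `time_s` column and one
#' `A:<channel>` / `B:<channel>` column per channel and subject.
#'
#' @param rec a \linkS4class{DyadRecording}.
#' @param path file path.
#' @return `writeDyadRecording` returns `path` invisibly;
#'   `readDyadRecording` returns the \linkS4class{DyadRecording}.
#' @export
writeDyadRecording <- function(rec, path) {
  stopifnot(is(rec, "DyadRecording"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# hyperibs dyad recording",
               sprintf("# fs=%.10g", rec@fs),
               sprintf("# dyad_id=%s", rec@dyadId),
               sprintf("# channels=%s", paste(rec@channelIds,
                                              collapse = ","))), con)
  tab <- data.frame((seq_len(nSamples(rec)) - 1L) / rec@fs,
                    t(rec@subjectA), t(rec@subjectB))
  names(tab) <- c("time_s", paste0("A:", rec@channelIds),
                  paste0("B:", rec@channelIds))
  suppressWarnings(write.table(tab, con, sep = "\t", row.names = FALSE,
                               quote = FALSE))
  invisible(path)
}

#' @rdname writeDyadRecording
#' @export
readDyadRecording <- function(path) {
  lines <- readLines(path)
  hdr <- readHeader(lines)
  if (is.null(hdr$fs)) stop("missing 'fs' header in ", path)
  fs <- as.numeric(hdr$fs)
  if (!is.finite(fs) || fs <= 0) stop("invalid sampling rate in ", path)
  body <- lines[!grepl("^#", lines)]
  tab <- read.table(text = body, header = TRUE, sep = "\t",
                    check.names = FALSE)
  bad <- which(!complete.cases(tab) | !apply(tab, 1L, function(r)
    all(is.finite(as.numeric(r)))))
  if (length(bad))
    stop("non-finite samples at data row(s) ", paste(head(bad, 5),
                                                     collapse = ", "))
  chans <- strsplit(hdr$channels %||% "ch1", ",")[[1]]
  a <- t(as.matrix(tab[, paste0("A:", chans), drop = FALSE]))
  b <- t(as.matrix(tab[, paste0("B:", chans), drop = FALSE]))
  dimnames(a) <- dimnames(b) <- NULL
  dyadRecording(a, b, fs = fs, channelIds = chans,
                dyadId = hdr$dyad_id %||% "dyad")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a coherence map as a delimited matrix
#'
#' Columns: `time_s`, `coi_s` (maximum valid period at that time), then one
#' column per grid period.
#'
#' @param map a \linkS4class{CoherenceMap}.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
writeCoherenceMap <- function(map, path) {
  stopifnot(is(map, "CoherenceMap"))
  tab <- data.frame(time_s = map@times, coi_s = map@coi, map@values)
  names(tab) <- c("time_s", "coi_s", sprintf("p%.4f", map@periods))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# hyperibs coherence map",
               sprintf("# periods=%s",
                       paste(sprintf("%.6g", map@periods), collapse = ","))),
             con)
  suppressWarnings(write.table(tab, con, sep = "\t", row.names = FALSE,
                               quote = FALSE))
  invisible(path)
}

#' Write a simulated cohort to a directory
#'
#' One delimited recording per dyad plus a `manifest.csv`
#' (`dyad_id, iteration, snr_db, seed, file`).
#'
#' @param cohort result of [simulateCohort()].
#' @param cfg the [simConfig()] that produced it.
#' @param dir output directory (created if needed).
#' @return The manifest data.frame, invisibly.
#' @export
writeCohort <- function(cohort, cfg, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  for (it in seq_along(cohort)) {
    for (d in seq_along(cohort[[it]])) {
      rec <- cohort[[it]][[d]]
      fn <- sprintf("iter%03d_%s.tsv", it, rec@dyadId)
      writeDyadRecording(rec, file.path(dir, fn))
      rows[[length(rows) + 1L]] <- data.frame(
        dyad_id = rec@dyadId, iteration = it, snr_db = cfg$snrDb,
        seed = cfg$seed, file = fn, stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, rows)
  write.table(manifest, file.path(dir, "manifest.csv"), sep = ",",
              row.names = FALSE, quote = FALSE)
  invisible(manifest)
}

#' Write window-level coherence contrasts as tidy CSV
#'
#' @param records data.frame from [windowWtcForDyad()] (possibly
#'   row-bound over dyads/iterations).
#' @param path file path.
#' @return `path`, invisibly.
#' @export
writeDeltaRecords <- function(records, path) {
  write.table(records, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

# small stable string hash (32-bit polynomial) for run manifests
strHash32 <- function(s) {
  h <- 5381
  for (b in utf8ToInt(s)) h <- (h * 33 + b) %% 4294967296
  sprintf("%08x", h)
}

writeRunManifest <- function(path, mode, config, seed) {
  cfgStr <- paste(deparse(config), collapse = "")
  jsonlite::write_json(
    list(tool = "hyperibs",
         version = as.character(utils::packageVersion("hyperibs")),
         mode = mode, seed = seed, configHash = strHash32(cfgStr),
         config = config, rVersion = R.version.string),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

cliUsage <- function() {
  cat("usage: hyperibs <simulate|ibs|table1> [options]\n",
      "  simulate --out DIR [--snr-db X] [--n-dyads N] [--n-iter N] [--seed N]\n",
      "  ibs --in FILE_OR_DIR --out CSV [--rest 0:60] [--task 60:300]\n",
      "      [--windows 50,60,...] [--offset 8]\n",
      "  table1 --out DIR [--config YAML] [--snr-db X,Y,...] [--n-dyads N]\n",
      "      [--n-iter N] [--seed N]\n",
      file = stderr())
}

parseArgv <- function(argv) {
  opts <- list()
  i <- 1L
  while (i <= length(argv)) {
    a <- argv[i]
    if (!startsWith(a, "--"))
      stop("unexpected argument: ", a)
    if (i == length(argv)) stop("missing value for ", a)
    opts[[substring(a, 3L)]] <- argv[i + 1L]
    i <- i + 2L
  }
  opts
}

parseRange <- function(s) {
  v <- as.numeric(strsplit(s, ":")[[1]])
  if (length(v) != 2L || anyNA(v)) stop("expected 'start:end', got ", s)
  v
}

#' Command-line entry point
#'
#' Thin dispatcher behind the `inst/cli/hyperibs` script. Runs one pipeline
#' stage (`simulate`, `ibs` or `table1`), writes its outputs and a JSON run
#' manifest (mode, seed, config and its hash, versions), and returns an
#' exit status: 0 on success, 2 on usage/validation errors.
#'
#' @param argv character vector of command-line arguments (subcommand
#'   first).
#' @return Integer exit status, invisibly.
#' @export
cliMain <- function(argv) {
  status <- tryCatch({
    if (!length(argv)) stop("no subcommand given")
    sub <- argv[1]
    opts <- parseArgv(argv[-1])
    seed <- as.integer(opts$seed %||% 1L)
    switch(sub,
      simulate = {
        if (is.null(opts$out)) stop("simulate requires --out")
        cfg <- simConfig(snrDb = as.numeric(opts[["snr-db"]] %||% 1.90),
                         nDyads = as.integer(opts[["n-dyads"]] %||% 25L),
                         nIterations = as.integer(opts[["n-iter"]] %||% 1L),
                         seed = seed)
        cohort <- simulateCohort(cfg)
        writeCohort(cohort, cfg, opts$out)
        writeRunManifest(file.path(opts$out, "manifest.json"), "simulate",
                         cfg[setdiff(names(cfg), c("design", "hrf"))], seed)
      },
      ibs = {
        if (is.null(opts[["in"]]) || is.null(opts$out))
          stop("ibs requires --in and --out")
        rest <- parseRange(opts$rest %||% "0:60")
        task <- parseRange(opts$task %||% "60:300")
        lay <- phaseLayout(rest[1], rest[2], task[1], task[2])
        lens <- as.numeric(strsplit(opts$windows %||%
                                      "50,60,70,80,90,100", ",")[[1]])
        scheme <- windowScheme(lengths = lens,
                               offset = as.numeric(opts$offset %||% 8))
        files <- if (dir.exists(opts[["in"]])) {
          list.files(opts[["in"]], pattern = "\\.tsv$", full.names = TRUE)
        } else opts[["in"]]
        if (!length(files)) stop("no recordings found under ", opts[["in"]])
        recs <- do.call(rbind, lapply(files, function(f)
          windowWtcForDyad(readDyadRecording(f), lay, scheme)))
        writeDeltaRecords(recs, opts$out)
        writeRunManifest(paste0(opts$out, ".manifest.json"), "ibs",
                         list(rest = rest, task = task, windows = lens,
                              inputs = basename(files)), seed)
      },
      table1 = {
        if (is.null(opts$out)) stop("table1 requires --out")
        cfg <- list(snrDb = c(1.90, 0.03, -2.19, -7.05, -10.15, -12.08),
                    nDyads = 25L, nIterations = 50L)
        if (!is.null(opts$config)) {
          if (!requireNamespace("yaml", quietly = TRUE))
            stop("the 'yaml' package is required for --config")
          cfg <- modifyList(cfg, yaml::read_yaml(opts$config))
        }
        if (!is.null(opts[["snr-db"]]))
          cfg$snrDb <- as.numeric(strsplit(opts[["snr-db"]], ",")[[1]])
        if (!is.null(opts[["n-dyads"]]))
          cfg$nDyads <- as.integer(opts[["n-dyads"]])
        if (!is.null(opts[["n-iter"]]))
          cfg$nIterations <- as.integer(opts[["n-iter"]])
        tab <- runTable1(snrDb = cfg$snrDb, nDyads = cfg$nDyads,
                         nIterations = cfg$nIterations, seed = seed)
        dir.create(opts$out, recursive = TRUE, showWarnings = FALSE)
        write.table(tab, file.path(opts$out, "table1.csv"), sep = ",",
                    row.names = FALSE, quote = FALSE)
        writeRunManifest(file.path(opts$out, "manifest.json"), "table1",
                         cfg, seed)
      },
      stop("unknown subcommand: ", sub)
    )
    0L
  }, error = function(e) {
    message("hyperibs: ", conditionMessage(e))
    cliUsage()
    2L
  })
  invisible(status)
}
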