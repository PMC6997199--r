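COUNT_COLS <- c("replicate", "generation", "stage", "sex", "genotype", "count")

validate_count_table <- function(tab) {
  if (!is.data.frame(tab)) stop("count table must be a data frame")
  miss <- setdiff(COUNT_COLS, names(tab))
  if (length(miss) > 0)
    stop("count table is missing column(s): ", paste(miss, collapse = ", "))
  bad <- which(!tab$genotype %in% GENOTYPES)
  if (length(bad) > 0)
    stop(sprintf("row %d: invalid genotype '%s' (expected AA, AB or BB)",
                 bad[1], tab$genotype[bad[1]]))
  bad <- which(!tab$stage %in% c("egg", "adult"))
  if (length(bad) > 0)
    stop(sprintf("row %d: invalid stage '%s'", bad[1], tab$stage[bad[1]]))
  bad <- which(!tab$sex %in% c("f", "m", "unknown"))
  if (length(bad) > 0)
    stop(sprintf("row %d: invalid sex '%s'", bad[1], tab$sex[bad[1]]))
  bad <- which(is.na(tab$count) | tab$count < 0 | tab$count != round(tab$count))
  if (length(bad) > 0)
    stop(sprintf("row %d: count '%s' is not a non-negative integer",
                 bad[1], tab$count[bad[1]]))
  key <- do.call(paste, tab[c("replicate", "generation", "stage", "sex",
                              "genotype")])
  if (anyDuplicated(key))
    stop("duplicate (replicate, generation, stage, sex, genotype) key: ",
         key[which(duplicated(key))[1]])
  invisible(tab)
}

#' Read and write genotype count tables
#'
#' Genotype count tables are TSV files with the header
#' `replicate generation stage sex genotype count` (stage `egg`/`adult`,
#' sex `f`/`m`/`unknown`, genotype `AA`/`AB`/`BB`). Lines starting with
#' `#` are treated as comments. Reading validates the table (column set,
#' value domains, non-negative integer counts, unique keys) and names the
#' offending row on failure; a file with only the header yields an empty
#' table. Write-then-read is the identity.
#'
#' @param path File path.
#' @return `read_count_table()` a validated data frame.
#' @export
read_count_table <- function(path) {
  tab <- utils::read.delim(path, comment.char = "#",
                           stringsAsFactors = FALSE)
  if (nrow(tab) == 0) {
    miss <- setdiff(COUNT_COLS, names(tab))
    if (length(miss) > 0)
      stop("count table is missing column(s): ", paste(miss, collapse = ", "))
    tab$count <- as.integer(tab$count)
    return(tab[COUNT_COLS])
  }
  validate_count_table(tab)
  tab$count <- as.integer(tab$count)
  tab$generation <- as.integer(tab$generation)
  tab[COUNT_COLS]
}

#' @rdname read_count_table
#' @param tab A genotype count table.
#' @param header Optional character vector of comment lines (written as
#'   `# ...` before the table), e.g. a config echo.
#' @export
write_count_table <- function(tab, path, header = NULL) {
  validate_count_table(tab[COUNT_COLS])
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste("#", header), con)
  utils::write.table(tab[COUNT_COLS], con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Export trajectories as a tidy TSV
#'
#' One row per replicate x generation x stage x sex x genotype with the
#' count, within-cell proportion, the (sex-pooled) alpha frequency of the
#' stage and the extinction flag; the configuration is echoed as `# key =
#' value` comment lines.
#'
#' @param trajectories A `trajectory` or list of them.
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_trajectories <- function(trajectories, path) {
  if (inherits(trajectories, "trajectory"))
    trajectories <- list(trajectories)
  cfg <- trajectories[[1]]$config
  header <- c(sprintf("K = %d", cfg$K),
              sprintf("n_generations = %d", cfg$n_generations),
              sprintf("initial_props = %s",
                      paste(signif(cfg$initial_props, 6), collapse = ",")),
              sprintf("sex_ratio = %g", cfg$sex_ratio),
              sprintf("freq_dep = %g", cfg$freq_dep),
              sprintf("seed = %d", cfg$seed))
  rows <- lapply(seq_along(trajectories), function(i) {
    tr <- trajectories[[i]]
    r <- tr$records
    totals <- stats::aggregate(count ~ generation + stage, data = r, sum)
    names(totals)[3] <- "cell_total"
    r <- merge(r, totals, by = c("generation", "stage"))
    r$proportion <- ifelse(r$cell_total > 0, r$count / r$cell_total, NA)
    p_by <- stats::aggregate(count ~ generation + stage + genotype,
                             data = r, sum)
    pa <- do.call(rbind, lapply(split(p_by, p_by[c("generation", "stage")]),
      function(d) {
        n <- stats::setNames(d$count, d$genotype)
        data.frame(generation = d$generation[1], stage = d$stage[1],
                   p_alpha = if (sum(n) > 0) allele_frequency(n) else NA)
      }))
    r <- merge(r, pa, by = c("generation", "stage"))
    data.frame(replicate = i, r[c("generation", "stage", "sex", "genotype",
                                  "count", "proportion", "p_alpha")],
               extinct = tr$extinct)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$replicate, out$generation, out$stage, out$sex,
                   match(out$genotype, GENOTYPES)), ]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste("#", header), con)
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a run manifest
#'
#' A JSON record from which every output of a command can be regenerated:
#' the command, the fully resolved configuration, the master seed, the
#' package version, a timestamp and the list of files written.
#'
#' @param command Character, the subcommand.
#' @param config A list (resolved configuration).
#' @param seed Master seed.
#' @param outputs Character vector of output paths.
#' @param path Manifest destination.
#' @export
write_manifest <- function(command, config, seed, outputs, path) {
  manifest <- list(
    command = command,
    config = config,
    seed = seed,
    package_version = as.character(utils::packageVersion("coelosim")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    outputs = outputs)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
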