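# Internal helpers: validation, seed substreams, config hashing.

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

assert_count <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 1 || x != round(x))
    stopf("'%s' must be a positive integer (got %s)", name,
          paste(format(x), collapse = ","))
  as.integer(x)
}

assert_fraction <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stopf("'%s' must be a fraction in [0, 1]", name)
  as.numeric(x)
}

assert_nonneg <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0)
    stopf("'%s' must be a non-negative number", name)
  as.numeric(x)
}

# Per-component substreams derived from one global seed, so regenerating one
# component does not reshuffle the others. Kept below 2^31 - 1.
derive_seed <- function(seed, stream) {
  seed <- as.numeric(seed)
  (abs(seed) * 131 + stream * 77003 + 17) %% 2147483629
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# md5 of a canonical text serialization; used to stamp output files.
config_hash <- function(config) {
  txt <- yaml::as.yaml(config)
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(txt, f)
  unname(tools::md5sum(f))
}

file_header <- function(config = NULL) {
  h <- if (is.null(config)) "" else paste0(" config_md5=", config_hash(config))
  sprintf("# psdregions %s%s", as.character(utils::packageVersion("psdregions")), h)
}

write_tsv <- function(df, path, config = NULL, digits = 15) {
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], function(x) formatC(x, digits = digits, format = "g"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(file_header(config), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                    check.names = FALSE, ...)
}
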