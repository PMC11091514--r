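#' Build a token vocabulary from training-window data
#'
#' One dense integer map per field (event names, medication names, medication
#' actions, services, hospitals, locations, urgency, whitespace-split
#' procedure-name tokens). Id 0 is reserved for padding and id 1 for unknown;
#' real tokens get ids 2.. ordered by descending frequency then
#' lexicographically, so the mapping is deterministic. Tokens seen fewer than
#' `min_count` times map to unknown. The vocabulary is frozen on return:
#' tokenizing never adds entries, so test-window data cannot grow it.
#'
#' @param cases Training-window case table.
#' @param observations Training-window observation table.
#' @param min_count Minimum token frequency to receive its own id.
#' @return An object of class `or_vocab`.
#' @export
build_vocab <- function(cases, observations, min_count = 1) {
  if (nrow(cases) == 0L)
    or_stopf("cannot build a vocabulary from an empty training set")
  fields <- list(
    event = observations$name[observations$stream == "event"],
    medication = observations$name[observations$stream == "medication"],
    action = observations$action[observations$stream == "medication"],
    service = cases$service,
    hospital = cases$hospital,
    location = cases$location,
    urgency = cases$urgency,
    procedure = unlist(strsplit(tolower(cases$procedure_name), "\\s+"))
  )
  maps <- lapply(fields, function(x) {
    x <- x[!is.na(x) & nzchar(x)]
    tab <- table(x)
    tab <- tab[tab >= min_count]
    toks <- if (length(tab)) names(tab)[order(-as.integer(tab), names(tab))] else character(0)
    ids <- c(0L, 1L, seq_along(toks) + 1L)
    names(ids) <- c("<pad>", "<unk>", toks)
    ids
  })
  v <- structure(list(maps = maps, min_count = min_count, frozen = TRUE),
                 class = "or_vocab")
  v$md5 <- vocab_digest(v)
  v
}

#' Tokenize labels with a frozen vocabulary
#'
#' @param vocab An [or_vocab].
#' @param field Field name (e.g. "event", "medication", "service").
#' @param x Character vector of labels.
#' @return Integer ids; labels absent from the map become the unknown id 1.
#' @export
tokenize <- function(vocab, field, x) {
  map <- vocab$maps[[field]]
  if (is.null(map)) or_stopf("unknown vocabulary field '%s'", field)
  id <- unname(map[x])
  id[is.na(id)] <- 1L
  as.integer(id)
}

# Reverse lookup: ids -> labels ("<unk>" for id 1).
#' @noRd
detokenize <- function(vocab, field, id) {
  map <- vocab$maps[[field]]
  names(map)[match(id, map)]
}

#' @export
print.or_vocab <- function(x, ...) {
  sizes <- vapply(x$maps, length, integer(1))
  cat(sprintf("<or_vocab> frozen, min_count %d\n", x$min_count))
  for (f in names(sizes)) cat(sprintf("  %-10s %d tokens\n", f, sizes[f]))
  invisible(x)
}

#' Write / read a vocabulary as JSON
#' @param vocab An [or_vocab].
#' @param path File path.
#' @return `write_vocab` returns `path` invisibly; `read_vocab` the vocab.
#' @export
write_vocab <- function(vocab, path) {
  payload <- list(min_count = vocab$min_count,
                  maps = lapply(vocab$maps, as.list))
  writeLines(jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA), path)
  invisible(path)
}

#' @rdname write_vocab
#' @export
read_vocab <- function(path) {
  payload <- jsonlite::fromJSON(readLines(path), simplifyVector = TRUE)
  maps <- lapply(payload$maps, function(m) {
    ids <- as.integer(unlist(m))
    names(ids) <- names(m)
    ids
  })
  v <- structure(list(maps = maps, min_count = as.integer(payload$min_count),
                      frozen = TRUE),
                 class = "or_vocab")
  v$md5 <- vocab_digest(v)
  v
}

# Stable digest of a vocabulary (used to detect model/vocab mismatch).
#' @noRd
vocab_digest <- function(vocab) {
  f <- tempfile()
  on.exit(unlink(f))
  write_vocab(vocab, f)
  unname(tools::md5sum(f))
}
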