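#' @title Logic-based network models
#' @description Construct a validated logic-based differential-equation
#'   (LDE) network model from species and reaction tables.
#'
#' @details
#' A model is defined by two tables.  The species table has columns
#' \describe{
#'   \item{name}{unique species identifier}
#'   \item{class}{reaction class driving the time constant:
#'     \code{"signaling"} (0.1 h), \code{"transcription"} (1 h) or
#'     \code{"translation"} (10 h); blank defaults to signaling}
#'   \item{y_init}{initial activity, default 0}
#'   \item{y_max}{maximal activity, default 1}
#'   \item{tau_override}{optional explicit time constant in hours,
#'     overriding the class default}
#' }
#' The reaction table has columns \code{rule}, \code{w}, \code{n},
#' \code{ec50}; blank parameter cells take the defaults
#' \code{w = 0.9}, \code{n = 1.4}, \code{ec50 = 0.6}.  Rules use the
#' grammar \code{"[!]A [&|] [!]B ... => target"}; a rule with an empty
#' left-hand side (\code{"=> A"}) declares \code{A} an input node driven
#' by a SOURCE reaction, whose weight is the input activity itself
#' (blank defaults to the baseline input level 0.25).
#'
#' @param species data.frame as described above (only \code{name} is
#'   mandatory).
#' @param reactions data.frame with at least a \code{rule} column.
#' @return an object of class \code{lde_network}.
#' @seealso [read_network_tables()], [simulate_network()]
#' @export
lde_network <- function(species, reactions) {
  species <- as.data.frame(species, stringsAsFactors = FALSE)
  reactions <- as.data.frame(reactions, stringsAsFactors = FALSE)
  if (!"name" %in% names(species)) stop("species table needs a 'name' column")
  if (!"rule" %in% names(reactions)) stop("reactions table needs a 'rule' column")

  nm <- trimws(as.character(species$name))
  if (anyDuplicated(nm))
    stop("duplicate species: ", paste(unique(nm[duplicated(nm)]), collapse = ", "))

  getcol <- function(df, col, default) {
    if (!col %in% names(df)) return(rep(default, nrow(df)))
    v <- df[[col]]
    if (is.character(v)) v[!nzchar(trimws(v))] <- NA
    v <- suppressWarnings(as.numeric(v))
    v[is.na(v)] <- default
    v
  }
  cls <- if ("class" %in% names(species)) trimws(as.character(species$class)) else rep("", nrow(species))
  cls[is.na(cls) | !nzchar(cls)] <- "signaling"
  bad <- setdiff(unique(cls), names(.tau_class))
  if (length(bad)) stop("unknown species class: ", paste(bad, collapse = ", "))
  tau <- unname(.tau_class[cls])
  tau_ov <- getcol(species, "tau_override", NA_real_)
  tau[!is.na(tau_ov)] <- tau_ov[!is.na(tau_ov)]

  sp <- data.frame(name = nm, class = cls,
                   y_init = getcol(species, "y_init", 0),
                   y_max = getcol(species, "y_max", 1),
                   tau = tau, stringsAsFactors = FALSE)
  if (any(sp$y_max <= 0)) stop("y_max must be > 0")
  if (any(sp$tau <= 0)) stop("tau must be > 0")
  if (any(sp$y_init < 0 | sp$y_init > sp$y_max))
    stop("y_init must lie in [0, y_max]")

  w <- getcol(reactions, "w", NA_real_)
  n <- getcol(reactions, "n", 1.4)
  ec50 <- getcol(reactions, "ec50", 0.6)

  rx <- vector("list", nrow(reactions))
  for (i in seq_len(nrow(reactions))) {
    pr <- .parse_rule(reactions$rule[i], i)
    wi <- w[i]
    if (is.na(wi)) wi <- if (pr$gate == "SOURCE") 0.25 else 0.9
    if (pr$gate != "SOURCE" && (wi <= 0 || wi > 1))
      stop("reaction ", i, ": w must lie in (0, 1]")
    if (n[i] <= 0) stop("reaction ", i, ": hill_n must be > 0")
    if (ec50[i] <= 0 || ec50[i] >= 1) stop("reaction ", i, ": ec50 must lie in (0, 1)")
    rx[[i]] <- list(target = pr$target, regulators = pr$regulators,
                    signs = pr$signs, gate = pr$gate,
                    w = wi, n = n[i], ec50 = ec50[i], rule = pr$rule)
  }

  refs <- unique(unlist(lapply(rx, function(r) c(r$target, r$regulators))))
  unknown <- setdiff(refs, sp$name)
  if (length(unknown))
    stop("rule references undeclared species: ", paste(unknown, collapse = ", "))

  inputs <- unique(vapply(Filter(function(r) r$gate == "SOURCE", rx),
                          `[[`, "", "target"))
  targets <- unique(vapply(rx, `[[`, "", "target"))
  orphan <- setdiff(sp$name, targets)
  if (length(orphan))
    stop("species with no reaction and not an input node: ",
         paste(orphan, collapse = ", "))

  structure(list(species = sp, reactions = rx, inputs = inputs),
            class = "lde_network")
}

.tau_class <- c(signaling = 0.1, transcription = 1, translation = 10)

# grammar: "[!]A [&|] [!]B ... => target"; empty LHS => SOURCE
.parse_rule <- function(rule, row = NA) {
  rule0 <- rule
  rule <- trimws(as.character(rule))
  where <- if (is.na(row)) "" else paste0(" (reactions row ", row, ")")
  parts <- strsplit(rule, "=>", fixed = TRUE)[[1]]
  if (length(parts) > 2 || !grepl("=>", rule, fixed = TRUE))
    stop("malformed rule", where, ": ", rule0)
  target <- trimws(parts[length(parts)])
  if (!nzchar(target) || grepl("[!&|[:space:]]", target))
    stop("malformed rule target", where, ": ", rule0)
  lhs <- if (length(parts) == 2) trimws(parts[1]) else ""
  if (!nzchar(lhs))
    return(list(target = target, regulators = character(0),
                signs = integer(0), gate = "SOURCE", rule = rule))
  has_and <- grepl("&", lhs, fixed = TRUE)
  has_or <- grepl("|", lhs, fixed = TRUE)
  if (has_and && has_or)
    stop("mixed & and | in one rule", where, ": ", rule0)
  toks <- trimws(strsplit(lhs, if (has_or) "|" else "&", fixed = TRUE)[[1]])
  if (any(!nzchar(toks))) stop("malformed rule", where, ": ", rule0)
  signs <- ifelse(startsWith(toks, "!"), -1L, 1L)
  regs <- sub("^!\\s*", "", toks)
  if (any(grepl("[!&|[:space:]]", regs)))
    stop("malformed rule regulator", where, ": ", rule0)
  gate <- if (length(regs) == 1L) "SINGLE" else if (has_or) "OR" else "AND"
  list(target = target, regulators = regs, signs = signs, gate = gate,
       rule = rule)
}

#' Read a network model from delimited tables
#'
#' Reads the two-table (species + reactions) description of a logic-based
#' network model, in the Netflux-style dialect documented in
#' [lde_network()].  The delimiter is inferred from the file extension
#' (\code{.tsv}/\code{.txt} tab, otherwise comma).
#'
#' @param species_file path to the species table.
#' @param reactions_file path to the reactions table.
#' @return an [lde_network] object.
#' @export
read_network_tables <- function(species_file, reactions_file) {
  rd <- function(path) {
    sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
    utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                      stringsAsFactors = FALSE, strip.white = TRUE,
                      comment.char = "#")
  }
  lde_network(rd(species_file), rd(reactions_file))
}

#' @export
print.lde_network <- function(x, ...) {
  ns <- nrow(x$species)
  nr <- length(x$reactions)
  cat("Logic-based ODE network model\n")
  cat(sprintf("  %d species, %d reactions, %d input nodes\n",
              ns, nr, length(x$inputs)))
  cat("  inputs:", paste(x$inputs, collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.lde_network <- function(object, ...) {
  cat("Species:\n")
  print(object$species, row.names = FALSE)
  cat("\nReactions:\n")
  for (r in object$reactions)
    cat(sprintf("  %-40s w=%.3g n=%.3g ec50=%.3g [%s]\n",
                r$rule, r$w, r$n, r$ec50, r$gate))
  invisible(object)
}
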