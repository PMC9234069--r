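## Shared fixture builders and independent oracles. Oracles deliberately use
## naive loops / base-R set algebra so they share no code path with the
## package implementation they check.

tmpfile <- function(lines, ext = ".tsv") {
  p <- tempfile(fileext = ext)
  writeLines(lines, p)
  p
}

write_map <- function(codes, descriptions = NULL) {
  lines <- if (is.null(descriptions)) codes else
    paste(codes, descriptions, sep = "\t")
  tmpfile(lines)
}

## brute-force prefix-scan oracle for code expansion: for every map code,
## test every pattern by character comparison after manual dot-stripping
oracle_expand <- function(patterns, map_codes, hierarchical,
                          ignore_case = FALSE) {
  strip <- function(x) {
    x <- trimws(x)
    while (length(x) && any(substring(x, nchar(x)) == ".")) {
      ends <- substring(x, nchar(x)) == "."
      x[ends] <- substr(x[ends], 1, nchar(x[ends]) - 1)
    }
    if (ignore_case) toupper(x) else x
  }
  pats <- unique(strip(patterns))
  pats <- pats[nchar(pats) > 0]
  hits <- character()
  for (mc in map_codes) {
    m <- strip(mc)
    for (p in pats) {
      ok <- if (hierarchical) substr(m, 1, nchar(p)) == p else m == p
      if (ok) {
        hits <- c(hits, mc)
        break
      }
    }
  }
  hits
}

## settings + definitions + maps of the bundled example, loaded once
example_world <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      st <- read_data_settings(example_data_settings())
      defset <- suppressWarnings(read_definition_table(
        example_definitions(), st, example_codemap_dir()))
      cache <<- list(settings = st, defset = defset)
    }
    cache
  }
})

## one harmonized synthetic cohort shared across tests (generated once)
shared_cohort <- local({
  cache <- NULL
  function(n = 200, seed = 424242, n_exclusion = 0) {
    key <- paste(n, seed, n_exclusion)
    if (is.null(cache) || cache$key != key) {
      w <- example_world()
      dir <- file.path(tempdir(), paste0("synthcohort_", n, "_", seed, "_",
                                         n_exclusion))
      res <- generate_cohort(synth_config(n = n, seed = seed,
                                          n_exclusion = n_exclusion), dir)
      f <- as.list(res$files)
      hz <- suppressWarnings(harmonize_all(
        f$main, f$metadata_html, w$defset, w$settings,
        f.hesin = f$hesin, f.hesin_diag = f$hesin_diag,
        f.hesin_oper = f$hesin_oper, f.gp_clinical = f$gp_clinical,
        f.gp_scripts = f$gp_scripts, f.death = f$death,
        f.death_cause = f$death_cause, f.withdrawal = f$withdrawal,
        extra_fields = c(54, 21003)))
      cache <<- list(key = key, files = f, truth = res$truth, hz = hz,
                     refs = hz$dfukb[, c("identifier", "f.53.0.0"),
                                     with = FALSE])
    }
    cache
  }
})

## ---- independent status oracle (set algebra over per-trait match sets) ----

oracle_strip_dots <- function(x) sub("\\.+$", "", trimws(x))

## participants matching one definition's own codes, scanning every episode
## table with naive loops
oracle_own_match <- function(def, lst, settings) {
  ids <- character()
  for (src in names(lst)) {
    eps <- lst[[src]]
    if (nrow(eps) == 0) next
    i <- match(src, settings$source_id)
    cls <- if (is.na(i)) eps$classification[1] else settings$classification[i]
    min_inst <- if (is.na(i)) 1L else settings$min_instances[i]
    hit <- rep(FALSE, nrow(eps))
    if (cls == "sr") {
      fid <- if (!is.na(i) && !is.na(settings$field_id[i]))
        settings$field_id[i] else as.integer(sub("^sr_", "", src))
      for (fs in def$field_specs) {
        if (fs$field_id != fid) next
        if (fs$any) {
          v <- suppressWarnings(as.numeric(eps$code))
          hit <- hit | is.na(v) | v >= 0
        } else {
          hit <- hit | eps$code %in% fs$codes
        }
      }
    } else if (cls == "ts") {
      canon <- vapply(def$conditions, `[[`, "", "canonical")
      hit <- eps$code %in% canon
    } else if (cls %in% names(def$code_sets)) {
      ic <- if (is.na(i)) FALSE else settings$ignore_case[i]
      fold <- function(x) if (ic) toupper(oracle_strip_dots(x)) else
        oracle_strip_dots(x)
      set <- fold(def$code_sets[[cls]])
      hit <- fold(eps$code) %in% set
    }
    if (!any(hit)) next
    cnt <- table(eps$identifier[hit])
    ids <- union(ids, names(cnt)[cnt >= min_inst])
  }
  ids
}

## include-closure of match sets
oracle_mstar <- function(defset, trait, lst, settings, memo = new.env()) {
  if (!is.null(memo[[trait]])) return(memo[[trait]])
  memo[[trait]] <- character()  # cycle guard (plans are acyclic anyway)
  d <- defset$definitions[[trait]]
  out <- oracle_own_match(d, lst, settings)
  for (inc in d$include_definitions) {
    out <- union(out, oracle_mstar(defset, inc, lst, settings, memo))
  }
  memo[[trait]] <- out
  out
}

## the composite case/control algebra: returns named status vector over ids
oracle_statuses <- function(defset, trait, lst, settings, ids) {
  memo <- new.env()
  d <- defset$definitions[[trait]]
  pop <- ids
  if (!is.na(d$study_population)) {
    pop <- intersect(pop, oracle_mstar(defset, d$study_population, lst,
                                       settings, memo))
  }
  cases <- intersect(pop, oracle_mstar(defset, trait, lst, settings, memo))
  excl_cases <- character()
  for (e in d$exclude_from_cases) {
    excl_cases <- union(excl_cases,
                        intersect(cases, oracle_mstar(defset, e, lst,
                                                      settings, memo)))
  }
  controls <- setdiff(pop, cases)
  excl_controls <- character()
  for (e in d$exclude_from_controls) {
    excl_controls <- union(excl_controls,
                           intersect(controls, oracle_mstar(defset, e, lst,
                                                            settings, memo)))
  }
  status <- setNames(rep(1L, length(pop)), pop)
  status[cases] <- 2L
  status[excl_cases] <- -2L
  status[excl_controls] <- -1L
  status
}

## random definition set over the toy code maps, for oracle-equivalence runs
random_defset <- function(seed) {
  set.seed(seed)
  w <- example_world()
  maps <- list(
    ICD10 = c("E10", "E11", "O24", "I48", "I50", "I110", "I21", "I25", "E78",
              "E119", "I480"),
    ICD9 = c("250", "25000", "4273", "428", "410", "272"),
    OPCS4 = c("K40", "K49", "K62", "K02", "K621"),
    READ2 = c("C10..", "C10F.", "G573.", "G58..", "C1001"),
    CTV3 = c("X40J5", "X40J6", "XaELQ", "G573.", "XE2QG", "X202k"),
    DMD = c("met00001", "sulf0001", "ins00001"))
  srs <- c("20002(1223)", "20002(1471, 1483)", "20002(1076)", "20003",
           "20003(1140884600)", "20004(1098)")
  tss <- c("6177=3", "2443=1[2976]", "4041=1")
  base <- paste0("T", 1:4)
  cellify <- function(pool, pmax = 3) {
    k <- sample(0:pmax, 1)
    if (k == 0) "" else paste(sample(pool, k), collapse = ", ")
  }
  rows <- lapply(base, function(tr) {
    c(TRAIT = tr, DESCRIPTION = "random",
      ICD10 = cellify(maps$ICD10), ICD9 = cellify(maps$ICD9, 2),
      OPCS4 = cellify(maps$OPCS4, 2), READ2 = cellify(maps$READ2, 2),
      CTV3 = cellify(maps$CTV3, 2), DMD = cellify(maps$DMD, 2),
      SR = cellify(srs, 2), TS = cellify(tss, 1),
      Study_population = "", Include_definitions = "",
      Exclude_from_cases = "", Exclude_from_controls = "")
  })
  pick <- function(pool, pmax = 2) {
    k <- sample(0:min(pmax, length(pool)), 1)
    if (k == 0) "" else paste(sample(pool, k), collapse = ", ")
  }
  inc <- pick(base)
  rest <- setdiff(base, strsplit(inc, ", ")[[1]])
  comp <- c(TRAIT = "C", DESCRIPTION = "random composite",
            ICD10 = cellify(maps$ICD10), ICD9 = "", OPCS4 = "", READ2 = "",
            CTV3 = "", DMD = "", SR = cellify(srs, 1), TS = "",
            Study_population = if (runif(1) < 0.3) sample(base, 1) else "",
            Include_definitions = inc,
            Exclude_from_cases = pick(rest, 1),
            Exclude_from_controls = pick(base, 1))
  tab <- do.call(rbind, c(rows, list(comp)))
  path <- tempfile(fileext = ".tsv")
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  suppressWarnings(read_definition_table(path, w$settings,
                                         example_codemap_dir()))
}
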