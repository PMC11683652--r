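---
title: "Tracing phrase diffusion in a threaded online health community"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracing phrase diffusion in a threaded online health community}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ohcdiffusion)
```

## The problem

Patients in moderated online health communities (OHCs) coin and pass on
figurative language — for example describing post-stroke fatigue as a
"legacy of stroke" — and tracing how such a phrase travels through the
community is a small but complete information-diffusion problem. The
archives these analyses run on are awkward in a specific way: posts are
listed in chronological order but carry **no timestamps**, and threads are
the unit of attention (a user who posts in a thread is assumed to read it,
including posts added later). `ohcdiffusion` packages the full manual
procedure as a reproducible pipeline: phrase-mention detection, superuser
classification, participation timelines, exposure-route classification,
diffusion-tree construction with mechanism labels, and diffusion depth —
plus a synthetic-forum generator that plants a known cascade so the whole
inference chain can be verified against ground truth.

## The data model

The only temporal information is the 1-based global post ordinal. All
"before/after" statements in the package compare these ordinals. Threads are
numbered 1-based by the ordinal of their earliest post; a thread's posts may
interleave with other threads'. Author identifiers are opaque,
case-sensitive strings. Thread membership means at least one post — the only
observable signal of participation (thread *reading* is unobservable; that
is precisely the lurking problem below).

## Mention detection

Matching is deliberately literal: the pattern lists keyword forms (e.g.
"legacy", "legacies") and explicit synonym/misspelling variants (e.g.
"heritage", "footprint"); tokenization lowercases and splits on
non-alphanumeric characters, so "delegacy" never matches and no stemming
surprises occur. Fuzzy matching is intentionally absent — a mention set must
be exactly reproducible from the pattern config. An automatic context rule
(a context term such as "stroke" or "fatigue" co-occurring in the same post,
or within a token window) pre-confirms candidates, but manual annotations
are authoritative in both directions: they can confirm what the rule missed
and reject what it over-claimed. Pattern configs are JSON; YAML was dropped
because no YAML parser is available in the supported dependency set and
hand-rolling one is worse than narrowing the interface.

The novelty check that in the original workflow ran against web search
engines and a national reference corpus is replaced by
`corpus_frequency()`: exact, case-insensitive, whitespace-normalized counts
of query strings over local text files. Zero counts everywhere set a novelty
flag for that corpus — and claim nothing beyond it.

## Superusers

Two definitions are implemented side by side, because both are in
circulation: the top 1% of users by total posts (ceiling, with all users
tied at the cutoff included) and a strict `> 100` posts threshold. The
strict-threshold form is the default: it is the definition that can be
audited row-by-row against a published participant table. The `min_posts`
classification is antitone in the threshold (raising it never adds a
superuser); this is a tested property.

A related ambiguity in cohort summaries: published mean ages for this kind
of cohort are sometimes only reproducible when caregiver rows are averaged
in, even when the surrounding text says otherwise. `summarize_cohort()`
therefore reports the all-rows means as the headline values (they are what
reproduces the packaged table's 49 and 45) and the survivor-only means
alongside, labeled, rather than resolving the contradiction silently.

## Exposure routes and the diffusion tree

Adoption events are the confirmed mentions grouped by author: the earliest
author is the root (single origination is assumed — a genuinely novel
construct is unlikely to be coined twice independently, and a config flag on
the generator exists for robustness studies of that assumption). For each
non-root adopter `u` with first use at ordinal `p`, the route precedence is:

1. **direct_metaphor_thread** — some thread holds a phrase post by an
   earlier adopter at an ordinal `< p`, and `u` posted in that thread. The
   adopter's own post there may fall before or after the phrase post:
   membership implies reading, including returning to the thread later.
2. **unrelated_co_thread** — `u` shares a thread of any topic with an
   earlier adopter, both users' first posts there preceding `p`.
3. **lurking_presumed** — no shared thread with any earlier adopter exists;
   the phrase must have been read without posting, and no source is named.

Source tie-breaking follows parsimony: the *earliest* qualifying exposure
wins (for the co-thread route, co-presence exists from the later of the two
first posts). A `tie_break = "latest"` policy is selectable for sensitivity
analysis; it changes only the named source, never the route.

The diffusion tree contains the adopters plus every distinct non-adopter
co-participant of a phrase-bearing thread (*recipients* — demonstrably
exposed users). Adoption edges carry mechanism labels mapped from routes:
direct exposure happens in threads where the source promoted their own
phrase (`self_promotion_exposure`); co-thread exposure is spreading along a
social tie (`social`); presumed lurkers attach to the root, flagged
`lurking_presumed` — the root authored the overwhelming majority of exposure
opportunities, making it the most parsimonious unnamed source. Spreading
edges link each phrase poster to each recipient of their phrase threads,
one edge per source–recipient pair. **Depth** is the length in edges of the
longest root-to-leaf path over all edges (the cascade-depth convention);
breadth (number of distinct recipients) is reported separately, because
"how far" and "how wide" are different facts. Depth is computed by memoized
DFS; the test suite checks it against an independent Bellman-Ford
longest-path oracle on every generated instance.

## The synthetic generator: a stated world

`generate_forum()` emulates exactly the structure the inference assumes, no
more: users get Zipf activity weights (exponent 1 by default, which makes
the top 1% of 500 users carry >10x their population share of posts — the
superuser skew the analysis leverages); threads are generated in
chronological order with shifted-Poisson sizes (minimum 1, mean 3 by
default, giving the real-forum mix of single-post and long threads); the
most active user originates the phrase in `origin_thread` (default 2,
mirroring the narrative the packaged fixture encodes); adopters thereafter
include the phrase once per thread they post in with probability
`self_promotion_rate` (default 0.3); every poster of a phrase-bearing
thread is exposed with certainty, every non-poster lurks onto it with
probability `lurk_prob` (default 0.1 — a study parameter, not an estimate:
no quantitative lurking prevalence exists to calibrate against); and a user
flips one adoption coin with probability `adoption_prob` (default 0.2) at
their **first** exposure.

Two semantics here were genuinely open and are worth stating plainly:

* **Adoption is decided once, at first exposure.** Under the alternative
  (a coin at every exposure), the true source of an adoption could be a
  later exposure than the earliest one, while the inference — which can only
  prefer the most parsimonious, earliest candidate — would systematically
  name the earlier source. Exact recovery would then be unattainable even in
  the noiseless world, for reasons that have nothing to do with the
  inference being wrong. The one-coin semantics is the reading under which
  "noiseless cascade ⇒ exact recovery" is a meaningful test of the code.
* **Recovery is scored against *expressed* adopters** — planted adopters
  with at least one phrase post. A silent adopter leaves no trace in the
  archive by construction; no archive-based procedure could recover them,
  and scoring against them would measure the world, not the method. The
  ground truth keeps all planted adoptions with an `expressed` flag, so the
  gap itself is measurable.

With `lurk_prob = 0`, inferred adoption edges equal planted edges exactly
(precision = recall = 1 across 50 seeds at 200 users / 500 threads — an
acceptance criterion). With lurking enabled, a lurking-planted adopter may
legitimately be classified as directly exposed — when they later genuinely
posted in a phrase thread before their own first use — but never with a
fabricated evidence thread; the route confusion matrix from
`recovery_metrics()` quantifies exactly this ambiguity. A green recovery
test therefore establishes that the inference is a correct reconstruction
*of worlds shaped like the generator's*: heavy-tailed activity, contiguous
threads, single origination, posting-certain exposure. It does not
establish robustness to community structure, user churn, multiple
independent coinages, or non-stationary activity — none of which the
generator models, by design.

## Numerical and degenerate-input choices

Percentages and mean ages round half-up to integers (matching how such
values are conventionally printed; base R's round-half-even would turn
49.5 into 49). An empty forum, an empty mention set, or a single-adopter
forum all flow through the pipeline producing empty-but-well-formed
artifacts and a warning, not errors. An empty post-count map classifies to
an empty superuser set. `recovery_metrics()` on an empty truth against an
empty inference returns precision = recall = 1 flagged `degenerate = TRUE`,
so sweeps over harsh parameter corners do not crash. Duplicate post
ordinals are a hard construction error (they would silently corrupt every
temporal comparison); they are also reported non-fatally by
`validate_forum()` for externally assembled containers.

## Limitations

The inference is deterministic given the archive — there is no probabilistic
cascade model and no likelihood over unobserved paths; `lurking_presumed` is
an explicit admission of unobservability, not an estimate. Broadcast-style
diffusion is out of scope (closed communities have no mass-media channel).
The packaged participant table and mini-forum are programmatically
constructed to be *consistent with* a published narrative; the original
archive is closed, so archive-scale totals (tens of thousands of posts) are
not reproduced here and are deliberately not asserted anywhere in the test
suite.
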