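---
title: "Methods: content-plus-frequency analysis of threaded health forums"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: content-plus-frequency analysis of threaded health forums}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Online communities for health behavior change (the motivating case is a
smoking-cessation forum) live or die by user engagement, and raw posting
frequency alone says little about *what* highly engaged members actually
contribute. forumscope implements a content-plus-frequency analysis for
threaded forum corpora: it stratifies users into engagement groups by
count-based metrics, infers each user's abstinence status from quit-date
event logs and in-message quit-duration signatures, assigns
behavior-change-technique (BCT) theme labels to messages with classifiers
over corpus-adapted distributional representations, scores sentiment
direction against a lexicon, and cross-tabulates content against
engagement group.

Everything below is the package's own account of the procedure, its
parameters and the design decisions taken where the design was genuinely
open.

# Engagement stratification

Three per-user per-year metrics define three engagement archetypes:

* **conversation initiators** — users rooting the most threads;
* **conversation attractors** — users whose posts draw the most replies;
* **frequent posters** — users posting the most messages.

`compute_profiles()` attributes a thread to the sender of its
earliest-timestamped message (ties broken by message id so the root is
unique), counts posts per calendar year (January 1 – December 31; the
source data carries no other natural boundary), and credits a reply to
its explicit `recipient_id` when present, otherwise to the thread rooter,
never to the sender themself. `select_top_users()` takes the top *k*
(default 3) per metric per year among users with a non-zero metric value;
ties resolve by higher post count, then lexicographic user id, making the
selection deterministic and order-invariant. With k = 3, 3 groups and a
16-year window this yields 3 × 3 × 16 = 144 selection slots;
summaries count slots, and the run manifest additionally reports the
number of distinct users behind them, because the same user can top a
group in several years.

All reported shares go through one rounding rule, `proportion()`:
round-half-up at the requested number of decimals. Half-up (rather than
R's banker's rounding) is what published percentage tables almost
invariably use, and a single shared rule makes every table reproducible
from the per-message files.

# Abstinence status

Users set quit dates that are kept in an event log; community tradition
also places a quit-duration signature ("13 days, 23 hours, 47 minutes and
51 seconds smoke free", often decorated with slashes) inside message
text. `status_per_user_year()` assesses each user at December 31 of each
active year: the log wins when it has a quit date on or before the
anchor; otherwise the maximum signature parsed from that year's messages
is used; users with neither signal are `UNKNOWN`.

Fixed constants make binning deterministic: 1 month := 30.44 days,
1 year := 365.25 days, half-open bins `[lower, upper)` for under 3
months, 3–6 months, 6 months–1 year, 1–2 years, over 2 years, plus
active smoker (flag-driven) and unknown. When several signatures
conflict within a year we take the maximum — a package decision for
determinism, not a claim about how conflicting signatures ought to be
adjudicated; the year-end anchor is likewise our reproducible choice.
Known limitation: for users without logs the year-end assessment
extrapolates from the last signed message, so a category boundary
falling inside that gap produces an off-by-one-bin error; the synthetic
recovery tests quantify this at 2–2.5%.

# Two-stage superposition embeddings

Forum messages are terse, so a distributional model trained on the forum
alone is weak. The package therefore trains skip-gram negative-sampling
(SGNS) term vectors on a large background corpus and adapts them to the
forum in two superposition (vector-addition) stages:

1. **stage-1 message vectors** — sum of the background vectors of each
   message's in-vocabulary tokens (multiplicity counted), unit-normalized;
2. **corpus term vectors** — for every forum term above a frequency
   floor, the sum of the stage-1 vectors of the messages containing it
   (presence, not multiplicity — a term either occurred in a message or
   did not), unit-normalized;
3. **stage-2 message vectors** — sum of corpus term vectors of the
   message's tokens, unit-normalized. These are the classifier features.

The cycle runs once by default (`superposition_cycle()` exposes the
iteration count). Stage 2 uses corpus term vectors only, not a blend
with background vectors — the term stage already encodes the background
information, and blending would double-count it. Term contributions are
uniform; we considered frequency damping and decided against it because
the stopword list and SGNS subsampling already control frequent-token
dominance, and uniform addition keeps the additivity invariant exact.

The key property of this construction is **neologism transfer**:
community coinages ("nicodemon", "sickarettes") never occur in the
background corpus, yet they receive corpus term vectors from the
messages around them, and those messages are anchored in background
space through their other tokens. The synthetic generator plants exactly
this situation and the tests verify the coinage lands nearer its anchor
vocabulary than the bulk of random term pairs.

SGNS is implemented in compiled code (single-threaded, own
linear-congruential generator) so that a given seed reproduces training
bit for bit on any platform. Defaults follow the algorithm's
conventions: window 5 (dynamically shrunk), 5 negative samples, 5
epochs, minimum frequency 5, subsampling threshold 1e-3, initial
learning rate 0.025 with linear decay. Dimensionality is the one
substantive choice: 500 suits full-scale corpora; the package default is
50, which keeps desk-scale corpora training in seconds without changing
neighborhood structure materially.

Numerical conventions: unit normalization after every stage (superposed
magnitudes otherwise track message length and term frequency and would
swamp a Gaussian classifier); messages with no in-vocabulary token keep
an all-zero vector and are flagged, and flagged messages are excluded
from labeling; normalization is idempotent and zero rows stay zero.
The tokenizer lowercases, splits on non-alphanumerics, drops tokens
under two characters, applies one configurable stopword list identically
to the background corpus and every forum stage, and (for embedding
vocabularies only, `drop_numeric`) discards free-standing number tokens,
which are unbounded types — quit-counter values, mostly — with no stable
distributional meaning.

# Theme classification

Messages are coded against the 16 high-level categories of the BCT
taxonomy (a message can carry several themes), using a manually
annotated subset as training data. Themes with fewer than
`min_positives` positive examples (default 30 — below that, 10-fold
stratification leaves ~3 positives per fold and validation is
meaningless) are dropped by `filter_themes()`; the report lists both
retained and dropped themes with counts.

Each retained theme gets an independent binary naive Bayes classifier
over the stage-2 vectors. The event model is Gaussian by default —
embedding components are continuous — with an equal-frequency
discretized multinomial alternative behind a flag. The decision
threshold is 0.5 on the positive posterior. `cross_validate()` uses
stratified folds driven by a recorded seed (assignment is computed from
sorted ids, so input order is irrelevant), reduces the fold count
automatically when a class is smaller than the fold count, and reports
precision, recall and F-measure **pooled** over held-out folds: the
metrics reconstruct exactly from one summed confusion matrix, which
makes them deterministic and auditable. Per-fold averaging is available
as a flag, and `glance()` reports both macro-averaged and
pooled-across-themes summaries because a single published P/R/F triple
can be read either way.

`cohen_kappa()` implements the standard chance-corrected agreement used
for system–rater and inter-coder reliability.

# Sentiment

`score_messages()` computes a dictionary ratio score: (positive hits −
negative hits) / token count, in [−1, 1], with the direction given by
the sign and zero mapping to neutral. The lexicon is pluggable (two
plain-text word lists, disjoint by construction); the package bundles a
small general-purpose list written for this package. No negation or
valence-shifter handling is attempted. Absolute direction shares on real
text are lexicon-dependent, so the tests rely on synthetic recovery and
on arithmetic identities, not on reproducing any particular dictionary.

# The synthetic study generator

`synth_config()` fixes the study conditions; `generate_forum()` and
`generate_background()` are fully deterministic under the seed, and
every sampled fact is emitted as ground truth. The generator emulates:

* **threaded structure** — roots and replies per archetype Poisson
  rates; replies choose threads in proportion to the rooter's
  reply-attraction propensity and name the rooter as recipient 70% of
  the time;
* **four archetypes** — initiators (30 threads/user/year), attractors
  (propensity 40, i.e. their threads draw replies an order of magnitude
  more readily), posters (~110 posts/year) and a background population
  (~10 posts/year), mixed 6/6/6/82 per hundred users;
* **theme-bearing vocabulary** — each message carries 3 rich themes
  (archetype-favored themes at double weight, which produces the
  per-group content contrasts) and, with probability 0.12, one of 8
  sparse themes; each true theme plants 3+ tokens of its
  10-token vocabulary, so theme presence is verifiable token by token.
  The 8 sparse themes exist precisely to exercise the
  insufficient-positives filter;
* **filler language** — a 2,500-type vocabulary with Zipf(1.0)
  rank-frequency law stands in for ordinary language; its high-frequency
  head plays the role of function words and is the natural stopword
  list (`fixture_stopwords()`);
* **neologisms** — excluded from the background corpus by construction
  and co-placed with a block of their anchor theme's tokens in forum
  messages;
* **sentiment** — a 70/20/10 positive/negative/neutral mixture injected
  as lexicon words (only positive words into positive messages, and so
  on), with the generator vocabulary kept disjoint from the lexicon;
* **quit trajectories** — 85% of users quit at a date spread over the 8
  years before the corpus end; 20% of quitters have an earlier, brief
  (5–28 day) abandoned attempt, and between that attempt's relapse and
  the next quit date no signature is emitted (a relapsed smoker's
  counter disappears); 57.6% of quitters carry their quit dates in the
  event log, the rest are recoverable only from message signatures —
  mirroring the reported share of users whose logs were incomplete.
  Active-smoker ground truth arises only in relapse gaps; no user is a
  permanent never-quitter with signatures.

Message length is negative-binomial (terse by design). The default
study fixture is two years, 100 users, ≈3,900 messages, a 200-message
annotation subset and a ≈100k-token background corpus — sizes chosen so
the full pipeline runs in about half a minute on one CPU while every
recovery statistic still has usable resolution.

What the generator does **not** emulate: real linguistic style and
polysemy, negated sentiment, topic drift over years, user churn,
non-stationary posting rates, and any demographic-behavior correlation.
Passing recovery tests therefore demonstrates that the machinery is
implemented correctly and sensitive at realistic signal strengths — not
that real-corpus accuracy would match the synthetic numbers.

# Pipeline, determinism and scale

`run_pipeline()` chains ingest → engagement → embeddings →
classification → sentiment → reporting, failing fast with a stage-named
error (inputs are checked before any training starts). One master seed
is split deterministically per stage and recorded, with the
configuration hash, in the run manifest; re-running a manifest
reproduces every table bit for bit. Seven artifacts are written: group
demographics, per-group theme prevalence, per-group sentiment shares,
the theme model report, per-message labels, per-message sentiment, and
the manifest. Every percentage in the tables reproduces from the
per-message files via `proportion()`.

Problem sizes used in the test suite: the default fixture above for
recovery properties; a 16-year, 50-user, low-rate corpus for the
selection arithmetic (144 slots); 100-message slices for brute-force
superposition oracles. The whole suite runs in under a minute; the
acceptance script in about half a minute.

# Known limitations

* The abstinence year-end anchor and the maximum rule for conflicting
  signatures are reproducible conventions, not validated against human
  adjudication.
* Lexicon sentiment has no negation handling; scores on real prose are
  dictionary-dependent.
* The superposition space is anisotropic at small scale: cosine
  percentiles are frequency-confounded, which is why the neologism
  check is phrased against the random-pair distribution of the same
  space rather than as an absolute threshold.
* Gaussian naive Bayes assumes componentwise normality of unit-norm
  superpositions; it is the faithful default, not the strongest possible
  classifier.
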