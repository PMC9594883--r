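// Single-threaded, seeded skip-gram / CBOW trainer with negative sampling.
// Whole-word mode stores one vector per vocabulary word; subword mode
// composes a word's input representation as the mean of its own vector and
// its character n-gram vectors, so unseen words can be embedded later from
// their n-grams alone.
// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <random>
using namespace Rcpp;

static inline double sigmoid_clip(double x) {
  if (x > 8.0) return 1.0 - 1e-8;
  if (x < -8.0) return 1e-8;
  return 1.0 / (1.0 + std::exp(-x));
}

// unigram^0.75 negative-sampling table
static std::vector<int> build_neg_table(const arma::vec& counts, int table_size) {
  std::vector<int> table(table_size);
  arma::vec pow_counts = arma::pow(counts, 0.75);
  double total = arma::accu(pow_counts);
  double cum = 0.0;
  int i = 0;
  for (int t = 0; t < table_size; ++t) {
    double target = (t + 0.5) / table_size * total;
    while (cum + pow_counts[i] < target && i < (int)counts.n_elem - 1) {
      cum += pow_counts[i];
      ++i;
    }
    table[t] = i;
  }
  return table;
}

// [[Rcpp::export]]
List cpp_train_embeddings(List docs, int vocab_size, NumericVector counts,
                          int dim, int window, int epochs, int negative,
                          bool cbow, List ngram_ids, int n_ngrams,
                          double lr0, int seed) {
  const int V = vocab_size;
  const int G = n_ngrams;            // 0 for whole-word mode
  const bool subword = G > 0;

  std::mt19937_64 rng(static_cast<uint64_t>(seed));
  std::uniform_real_distribution<double> runif(0.0, 1.0);

  // input rows: V word rows followed by G n-gram rows; outputs word-level
  arma::mat Win(V + G, dim), Wout(V, dim, arma::fill::zeros);
  for (arma::uword r = 0; r < Win.n_rows; ++r)
    for (int c = 0; c < dim; ++c)
      Win(r, c) = (runif(rng) - 0.5) / dim;

  // per-word row sets (word itself + its n-grams, 0-based rows into Win)
  std::vector<std::vector<int>> rows_of(V);
  for (int w = 0; w < V; ++w) {
    rows_of[w].push_back(w);
    if (subword) {
      IntegerVector ng = ngram_ids[w];
      for (int j = 0; j < ng.size(); ++j) rows_of[w].push_back(V + ng[j] - 1);
    }
  }

  arma::vec cnt(counts.begin(), counts.size());
  std::vector<int> neg_table = build_neg_table(cnt, 100000);
  std::uniform_int_distribution<int> rtab(0, (int)neg_table.size() - 1);
  std::uniform_int_distribution<int> rwin(1, window);

  long long total_words = 0;
  for (int d = 0; d < docs.size(); ++d)
    total_words += ((IntegerVector)docs[d]).size();
  long long budget = total_words * (long long)epochs;
  long long processed = 0;

  arma::rowvec hidden(dim), errvec(dim);

  for (int ep = 0; ep < epochs; ++ep) {
    for (int d = 0; d < docs.size(); ++d) {
      IntegerVector doc = docs[d];
      int n = doc.size();
      for (int t = 0; t < n; ++t) {
        double lr = lr0 * std::max(1e-4, 1.0 - (double)processed / (budget + 1));
        ++processed;
        int b = rwin(rng);
        int lo = std::max(0, t - b), hi = std::min(n - 1, t + b);

        if (!cbow) {
          // skip-gram: center predicts each context word
          int center = doc[t] - 1;
          const std::vector<int>& rws = rows_of[center];
          hidden.zeros();
          for (int r : rws) hidden += Win.row(r);
          hidden /= (double)rws.size();
          for (int c = lo; c <= hi; ++c) {
            if (c == t) continue;
            int ctx = doc[c] - 1;
            errvec.zeros();
            for (int s = 0; s <= negative; ++s) {
              int target; double label;
              if (s == 0) { target = ctx; label = 1.0; }
              else {
                target = neg_table[rtab(rng)];
                if (target == ctx) continue;
                label = 0.0;
              }
              double f = sigmoid_clip(arma::dot(hidden, Wout.row(target)));
              double g = lr * (label - f);
              errvec += g * Wout.row(target);
              Wout.row(target) += g * hidden;
            }
            arma::rowvec upd = errvec / (double)rws.size();
            for (int r : rws) Win.row(r) += upd;
            hidden.zeros();
            for (int r : rws) hidden += Win.row(r);
            hidden /= (double)rws.size();
          }
        } else {
          // CBOW: mean of context representations predicts the center
          int center = doc[t] - 1;
          std::vector<int> ctx_words;
          for (int c = lo; c <= hi; ++c)
            if (c != t) ctx_words.push_back(doc[c] - 1);
          if (ctx_words.empty()) continue;
          hidden.zeros();
          int n_rows_tot = 0;
          for (int w : ctx_words)
            for (int r : rows_of[w]) { hidden += Win.row(r); ++n_rows_tot; }
          hidden /= (double)n_rows_tot;
          errvec.zeros();
          for (int s = 0; s <= negative; ++s) {
            int target; double label;
            if (s == 0) { target = center; label = 1.0; }
            else {
              target = neg_table[rtab(rng)];
              if (target == center) continue;
              label = 0.0;
            }
            double f = sigmoid_clip(arma::dot(hidden, Wout.row(target)));
            double g = lr * (label - f);
            errvec += g * Wout.row(target);
            Wout.row(target) += g * hidden;
          }
          arma::rowvec upd = errvec / (double)n_rows_tot;
          for (int w : ctx_words)
            for (int r : rows_of[w]) Win.row(r) += upd;
        }
      }
    }
  }

  // composed per-word vectors (mean over word + n-gram rows in subword mode)
  arma::mat word_vec(V, dim);
  for (int w = 0; w < V; ++w) {
    arma::rowvec acc(dim, arma::fill::zeros);
    for (int r : rows_of[w]) acc += Win.row(r);
    word_vec.row(w) = acc / (double)rows_of[w].size();
  }

  List out = List::create(_["vectors"] = wrap(word_vec));
  if (subword) {
    arma::mat ngram_vec = Win.rows(V, V + G - 1);
    out["ngram_vectors"] = wrap(ngram_vec);
  }
  return out;
}
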