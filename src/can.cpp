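// Context aggregation network: dilated 3x3 convolutions with per-channel
// adaptive normalization and leaky rectifiers, trained by Adam on an MSE
// regression loss. Feature maps are stored as (channels x pixels) float
// matrices with pixel index p = y + S*x (column-major images of side S);
// convolutions are evaluated as im2col + GEMM.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace Rcpp;
using arma::fmat;
using arma::fvec;

namespace {

struct Layer {
  fmat W;       // conv3: C_out x 9*C_in; conv1: 1 x C_in
  fvec b;       // C_out
  fvec s, o;    // adaptive normalization scale / offset (conv3 only)
  int dil = 1;
  float slope = 0.0f;
  bool conv1 = false;
  bool instance = false;  // standardize each channel map before the affine
};

// gradients / Adam moments share the Layer shape
struct Moments {
  fmat W;
  fvec b, s, o;
  void zero_like(const Layer& L) {
    W.zeros(L.W.n_rows, L.W.n_cols);
    b.zeros(L.b.n_elem);
    s.zeros(L.s.n_elem);
    o.zeros(L.o.n_elem);
  }
};

// X(k-block, p) = A(:, p shifted by the k-th (dy,dx) offset), zero padded.
void im2col(const fmat& A, int S, int d, fmat& X) {
  const int C = A.n_rows;
  X.zeros(9 * C, S * (size_t)S);
  int k = 0;
  for (int dx = -d; dx <= d; dx += d) {
    for (int dy = -d; dy <= d; dy += d) {
      const int x0 = std::max(0, -dx), x1 = S - 1 - std::max(0, dx);
      const int y0 = std::max(0, -dy), y1 = S - 1 - std::max(0, dy);
      if (y1 >= y0)
        for (int x = x0; x <= x1; ++x)
          X.submat(k * C, S * x + y0, (k + 1) * C - 1, S * x + y1) =
              A.cols(S * (x + dx) + y0 + dy, S * (x + dx) + y1 + dy);
      ++k;
      if (d == 0) break;  // defensive; dilation is always >= 1
    }
    if (d == 0) break;
  }
}

// scatter-add transpose of im2col: dA(:, shifted p) += G(k-block, p)
void col2im_add(const fmat& G, int S, int d, fmat& dA) {
  const int C = dA.n_rows;
  int k = 0;
  for (int dx = -d; dx <= d; dx += d) {
    for (int dy = -d; dy <= d; dy += d) {
      const int x0 = std::max(0, -dx), x1 = S - 1 - std::max(0, dx);
      const int y0 = std::max(0, -dy), y1 = S - 1 - std::max(0, dy);
      if (y1 >= y0)
        for (int x = x0; x <= x1; ++x)
          dA.cols(S * (x + dx) + y0 + dy, S * (x + dx) + y1 + dy) +=
              G.submat(k * C, S * x + y0, (k + 1) * C - 1, S * x + y1);
      ++k;
    }
  }
}

std::vector<Layer> parse_layers(const List& layers) {
  std::vector<Layer> net;
  for (int i = 0; i < layers.size(); ++i) {
    List li = layers[i];
    Layer L;
    L.W = as<fmat>(wrap(as<arma::mat>(li["W"])));
    L.b = as<fvec>(wrap(as<arma::vec>(li["b"])));
    L.conv1 = as<std::string>(li["type"]) == "conv1";
    if (!L.conv1) {
      L.s = as<fvec>(wrap(as<arma::vec>(li["s"])));
      L.o = as<fvec>(wrap(as<arma::vec>(li["o"])));
      L.dil = as<int>(li["dilation"]);
      L.slope = (float)as<double>(li["slope"]);
      if (li.containsElementNamed("norm"))
        L.instance = as<std::string>(li["norm"]) == "instance";
    }
    net.push_back(std::move(L));
  }
  return net;
}

List dump_layers(const std::vector<Layer>& net, const List& tmpl) {
  List out(net.size());
  for (size_t i = 0; i < net.size(); ++i) {
    List li = clone(as<List>(tmpl[i]));
    li["W"] = wrap(arma::conv_to<arma::mat>::from(net[i].W));
    li["b"] = wrap(arma::conv_to<arma::vec>::from(net[i].b));
    if (!net[i].conv1) {
      li["s"] = wrap(arma::conv_to<arma::vec>::from(net[i].s));
      li["o"] = wrap(arma::conv_to<arma::vec>::from(net[i].o));
    }
    out[i] = li;
  }
  return out;
}

// forward pass; when caches are supplied, stores per-layer inputs, pre-norm
// conv outputs and (when `cols` is non-null) the im2col matrices for reuse
// in backpropagation
fmat forward(const std::vector<Layer>& net, const fmat& input, int S,
             std::vector<fmat>* inputs, std::vector<fmat>* zs,
             std::vector<fmat>* cols, std::vector<fvec>* sigs = nullptr) {
  fmat A = input;
  fmat X;
  for (size_t l = 0; l < net.size(); ++l) {
    const Layer& L = net[l];
    if (inputs) inputs->push_back(A);
    if (L.conv1) {
      fmat Z = L.W * A;
      Z.each_col() += L.b;
      if (zs) zs->push_back(Z);
      A = std::move(Z);
    } else {
      fmat* Xp = &X;
      if (cols) {
        cols->emplace_back();
        Xp = &cols->back();
      }
      im2col(A, S, L.dil, *Xp);
      fmat Z = L.W * (*Xp);
      Z.each_col() += L.b;
      if (L.instance) {
        // standardize each channel map, then apply the affine
        fvec mu = arma::mean(Z, 1);
        fvec sg = arma::stddev(Z, 1, 1) + 1e-5f;
        Z.each_col() -= mu;
        Z.each_col() /= sg;
        if (sigs) sigs->push_back(sg);
      } else if (sigs) {
        sigs->push_back(fvec());
      }
      fmat N = Z;
      if (zs) zs->push_back(std::move(Z));
      N.each_col() %= L.s;
      N.each_col() += L.o;
      // leaky rectifier
      A = std::move(N);
      A.transform([&L](float v) { return v > 0.0f ? v : L.slope * v; });
      // Z (pre-norm) lives in the cache; N is rebuilt from it in backward
    }
  }
  return A;
}

void backward(const std::vector<Layer>& net, const std::vector<fmat>& inputs,
              const std::vector<fmat>& zs, const std::vector<fmat>& cols,
              const std::vector<fvec>& sigs, const fmat& dOut, int S,
              std::vector<Moments>& grad) {
  fmat dA = dOut;
  fmat X;
  size_t ci = cols.size();  // conv3 count; walk backwards through the cache
  for (int l = (int)net.size() - 1; l >= 0; --l) {
    const Layer& L = net[l];
    if (L.conv1) {
      grad[l].W += dA * inputs[l].t();
      grad[l].b += arma::sum(dA, 1);
      dA = L.W.t() * dA;
    } else {
      --ci;
      const fmat& Z = zs[l];
      // N = s*Z + o decides the rectifier branch
      fmat dN = dA;
      for (arma::uword c = 0; c < Z.n_rows; ++c) {
        const float sc = L.s(c), oc = L.o(c), sl = L.slope;
        const float* zr = Z.colptr(0) + c;  // strided row access
        float* dr = dN.colptr(0) + c;
        const arma::uword nr = Z.n_rows;
        for (arma::uword p = 0; p < Z.n_cols; ++p) {
          if (sc * zr[p * nr] + oc <= 0.0f) dr[p * nr] *= sl;
        }
      }
      grad[l].s += arma::sum(dN % Z, 1);
      grad[l].o += arma::sum(dN, 1);
      fmat dZ = std::move(dN);
      dZ.each_col() %= L.s;
      if (L.instance) {
        // gradient through per-channel standardization (population stats)
        const fvec& sg = sigs[l];
        fvec m1 = arma::mean(dZ, 1);
        fvec m2 = arma::mean(dZ % Z, 1);
        fmat corr = Z;
        corr.each_col() %= m2;
        dZ.each_col() -= m1;
        dZ -= corr;
        dZ.each_col() /= sg;
      }
      const fmat* Xp;
      if (!cols.empty()) {
        Xp = &cols[ci];
      } else {
        im2col(inputs[l], S, L.dil, X);
        Xp = &X;
      }
      grad[l].W += dZ * Xp->t();
      grad[l].b += arma::sum(dZ, 1);
      fmat G = L.W.t() * dZ;
      dA.zeros(inputs[l].n_rows, inputs[l].n_cols);
      col2im_add(G, S, L.dil, dA);
    }
  }
}

void adam_update(fmat& w, const fmat& g, fmat& m, fmat& v, float lr, int t) {
  const float b1 = 0.9f, b2 = 0.999f, eps = 1e-8f;
  m = b1 * m + (1.0f - b1) * g;
  v = b2 * v + (1.0f - b2) * (g % g);
  const float corr1 = 1.0f - std::pow(b1, (float)t);
  const float corr2 = 1.0f - std::pow(b2, (float)t);
  w -= lr * (m / corr1) / (arma::sqrt(v / corr2) + eps);
}

void adam_update(fvec& w, const fvec& g, fvec& m, fvec& v, float lr, int t) {
  const float b1 = 0.9f, b2 = 0.999f, eps = 1e-8f;
  m = b1 * m + (1.0f - b1) * g;
  v = b2 * v + (1.0f - b2) * (g % g);
  const float corr1 = 1.0f - std::pow(b1, (float)t);
  const float corr2 = 1.0f - std::pow(b2, (float)t);
  w -= lr * (m / corr1) / (arma::sqrt(v / corr2) + eps);
}

fmat as_map(const NumericMatrix& img) {
  arma::mat m = as<arma::mat>(wrap(img));
  fmat f = arma::conv_to<fmat>::from(m);
  f.reshape(1, f.n_elem);  // column-major flatten: p = row + S*col
  return f;
}

double mse(const fmat& pred, const fmat& lab) {
  fmat d = pred - lab;
  return arma::accu(d % d) / (double)d.n_elem;
}

}  // namespace

// [[Rcpp::export]]
NumericMatrix can_forward_cpp(List layers, NumericMatrix input) {
  std::vector<Layer> net = parse_layers(layers);
  const int S = input.nrow();
  if (input.ncol() != S) stop("input image must be square");
  fmat out = forward(net, as_map(input), S, nullptr, nullptr, nullptr);
  arma::mat om = arma::conv_to<arma::mat>::from(out);
  om.reshape(S, S);
  return wrap(om);
}

// [[Rcpp::export]]
List can_train_cpp(List layers, List train_in, List train_lab,
                   List val_in, List val_lab, IntegerMatrix order,
                   NumericVector lr_schedule, int batch_size) {
  std::vector<Layer> net = parse_layers(layers);
  const int n_train = train_in.size();
  const int n_val = val_in.size();
  const int epochs = order.nrow();
  if (n_train == 0) stop("empty training split");
  NumericMatrix first = train_in[0];
  const int S = first.nrow();

  std::vector<fmat> tri(n_train), trl(n_train), vai(n_val), val(n_val);
  for (int i = 0; i < n_train; ++i) {
    tri[i] = as_map(train_in[i]);
    trl[i] = as_map(train_lab[i]);
  }
  for (int i = 0; i < n_val; ++i) {
    vai[i] = as_map(val_in[i]);
    val[i] = as_map(val_lab[i]);
  }

  std::vector<Moments> grad(net.size()), m1(net.size()), m2(net.size());
  for (size_t l = 0; l < net.size(); ++l) {
    grad[l].zero_like(net[l]);
    m1[l].zero_like(net[l]);
    m2[l].zero_like(net[l]);
  }

  // keep the im2col cache only when it fits comfortably in memory
  size_t conv3_ch = 1;
  double cache_bytes = 0.0;
  for (const Layer& L : net)
    if (!L.conv1) {
      cache_bytes += 9.0 * conv3_ch * S * (double)S * sizeof(float);
      conv3_ch = L.W.n_rows;
    }
  const bool cache_cols = cache_bytes < 6e8;

  auto val_loss = [&]() {
    if (n_val == 0) return NA_REAL;
    double acc = 0.0;
    for (int i = 0; i < n_val; ++i)
      acc += mse(forward(net, vai[i], S, nullptr, nullptr, nullptr), val[i]);
    return acc / n_val;
  };

  NumericVector train_log(epochs), val_log(epochs + 1);
  val_log[0] = val_loss();

  if (lr_schedule.size() != epochs) stop("lr schedule length != epochs");
  int t = 0;
  for (int e = 0; e < epochs; ++e) {
    const float lr = (float)lr_schedule[e];
    double epoch_loss = 0.0;
    int done = 0;
    while (done < n_train) {
      const int nb = std::min(batch_size, n_train - done);
      for (size_t l = 0; l < net.size(); ++l) grad[l].zero_like(net[l]);
      for (int j = 0; j < nb; ++j) {
        const int idx = order(e, done + j) - 1;
        if (idx < 0 || idx >= n_train) stop("bad order index");
        std::vector<fmat> inputs, zs, cols;
        std::vector<fvec> sigs;
        fmat pred = forward(net, tri[idx], S, &inputs, &zs,
                            cache_cols ? &cols : nullptr, &sigs);
        epoch_loss += mse(pred, trl[idx]);
        fmat dOut = 2.0f * (pred - trl[idx]) / (float)pred.n_elem;
        backward(net, inputs, zs, cols, sigs, dOut, S, grad);
      }
      ++t;
      const float scale = 1.0f / (float)nb;
      for (size_t l = 0; l < net.size(); ++l) {
        adam_update(net[l].W, grad[l].W * scale, m1[l].W, m2[l].W, lr, t);
        adam_update(net[l].b, grad[l].b * scale, m1[l].b, m2[l].b, lr, t);
        if (!net[l].conv1) {
          adam_update(net[l].s, grad[l].s * scale, m1[l].s, m2[l].s, lr, t);
          adam_update(net[l].o, grad[l].o * scale, m1[l].o, m2[l].o, lr, t);
        }
      }
      done += nb;
    }
    train_log[e] = epoch_loss / n_train;
    val_log[e + 1] = val_loss();
    Rcpp::checkUserInterrupt();
  }

  return List::create(_["layers"] = dump_layers(net, layers),
                      _["train_loss"] = train_log,
                      _["val_loss"] = val_log);
}
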