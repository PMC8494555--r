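// Lossless codec primitives: CRC-32/Adler-32 checksums, canonical Huffman
// code construction, byte-alphabet Huffman coding, LZ77 tokenization with a
// hash-chain index, a raw DEFLATE (RFC 1951) encoder emitting dynamic-Huffman
// blocks with stored-block fallback, and a conformant inflater supporting
// stored, fixed-Huffman and dynamic-Huffman blocks.
//
// Bit conventions follow RFC 1951: bytes are filled LSB-first; Huffman codes
// are emitted most-significant code bit first.

#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <queue>
#include <algorithm>

using namespace Rcpp;

// ---------------------------------------------------------------- checksums

static uint32_t crc_table[256];
static bool crc_table_ready = false;

static void crc_init() {
  for (uint32_t n = 0; n < 256; ++n) {
    uint32_t c = n;
    for (int k = 0; k < 8; ++k)
      c = (c & 1) ? 0xEDB88320u ^ (c >> 1) : (c >> 1);
    crc_table[n] = c;
  }
  crc_table_ready = true;
}

static uint32_t crc32_bytes(const uint8_t* buf, size_t len) {
  if (!crc_table_ready) crc_init();
  uint32_t c = 0xFFFFFFFFu;
  for (size_t i = 0; i < len; ++i)
    c = crc_table[(c ^ buf[i]) & 0xFF] ^ (c >> 8);
  return c ^ 0xFFFFFFFFu;
}

// [[Rcpp::export]]
double cpp_crc32(RawVector data) {
  return (double) crc32_bytes(RAW(data), data.size());
}

// [[Rcpp::export]]
double cpp_adler32(RawVector data) {
  const uint32_t MOD = 65521u;
  uint32_t s1 = 1, s2 = 0;
  for (R_xlen_t i = 0; i < data.size(); ++i) {
    s1 = (s1 + data[i]) % MOD;
    s2 = (s2 + s1) % MOD;
  }
  return (double) ((s2 << 16) | s1);
}

// ------------------------------------------------------- Huffman code build

// Optimal prefix-code lengths from symbol frequencies (standard Huffman
// construction, deterministic tie-breaking by node creation order), followed
// by a length-limiting pass that clamps to max_bits and restores the Kraft
// equality constraint by demoting the deepest still-promotable codes.
static std::vector<int> huffman_lengths(const std::vector<double>& freq,
                                        int max_bits) {
  int n = (int) freq.size();
  std::vector<int> len(n, 0);
  std::vector<int> used;
  for (int i = 0; i < n; ++i) if (freq[i] > 0) used.push_back(i);
  if (used.empty()) return len;
  if (used.size() == 1) { len[used[0]] = 1; return len; }

  // nodes: 0..n-1 leaves, then internal
  struct Node { double f; int order; int idx; };
  struct Cmp {
    bool operator()(const Node& a, const Node& b) const {
      if (a.f != b.f) return a.f > b.f;
      return a.order > b.order;
    }
  };
  std::priority_queue<Node, std::vector<Node>, Cmp> pq;
  std::vector<int> left, right; // children of internal nodes
  int order = 0;
  for (int s : used) pq.push({freq[s], order++, s});
  int next_internal = n;
  std::vector<int> lch, rch;
  while (pq.size() > 1) {
    Node a = pq.top(); pq.pop();
    Node b = pq.top(); pq.pop();
    lch.push_back(a.idx); rch.push_back(b.idx);
    pq.push({a.f + b.f, order++, next_internal++});
  }
  // depth-first depth assignment
  int root = next_internal - 1;
  std::vector<std::pair<int,int> > stack; // idx, depth
  stack.push_back(std::make_pair(root, 0));
  while (!stack.empty()) {
    std::pair<int,int> t = stack.back(); stack.pop_back();
    if (t.first < n) { len[t.first] = std::max(1, t.second); continue; }
    int k = t.first - n;
    stack.push_back(std::make_pair(lch[k], t.second + 1));
    stack.push_back(std::make_pair(rch[k], t.second + 1));
  }

  // length-limit to max_bits (needed for DEFLATE trees)
  bool over = false;
  for (int s : used) if (len[s] > max_bits) over = true;
  if (over) {
    for (int s : used) if (len[s] > max_bits) len[s] = max_bits;
    // Kraft sum scaled by 2^max_bits must be <= 2^max_bits
    long long cap = 1LL << max_bits;
    long long ksum = 0;
    for (int s : used) ksum += 1LL << (max_bits - len[s]);
    while (ksum > cap) {
      // demote the deepest code shallower than max_bits (smallest overshoot)
      int best = -1;
      for (int s : used)
        if (len[s] < max_bits && (best < 0 || len[s] > len[best])) best = s;
      ksum -= 1LL << (max_bits - len[best] - 1);
      len[best] += 1;
    }
  }
  return len;
}

// [[Rcpp::export]]
IntegerVector cpp_huffman_lengths(NumericVector freqs, int max_bits) {
  std::vector<double> f(freqs.begin(), freqs.end());
  std::vector<int> len = huffman_lengths(f, max_bits);
  return IntegerVector(len.begin(), len.end());
}

// canonical codes from lengths (RFC 1951 rule: shorter first, ties by symbol)
static void canonical_codes(const std::vector<int>& len,
                            std::vector<uint32_t>& code) {
  int n = (int) len.size();
  code.assign(n, 0);
  int maxlen = 0;
  for (int l : len) maxlen = std::max(maxlen, l);
  if (maxlen == 0) return;
  std::vector<int> bl_count(maxlen + 1, 0);
  for (int l : len) if (l > 0) bl_count[l]++;
  std::vector<uint32_t> next_code(maxlen + 2, 0);
  uint32_t c = 0;
  for (int bits = 1; bits <= maxlen; ++bits) {
    c = (c + bl_count[bits - 1]) << 1;
    next_code[bits] = c;
  }
  for (int s = 0; s < n; ++s)
    if (len[s] > 0) code[s] = next_code[len[s]]++;
}

// [[Rcpp::export]]
IntegerVector cpp_canonical_codes(IntegerVector lengths) {
  std::vector<int> len(lengths.begin(), lengths.end());
  std::vector<uint32_t> code;
  canonical_codes(len, code);
  return IntegerVector(code.begin(), code.end());
}

// -------------------------------------------------------------- bit writer

struct BitWriter {
  std::vector<uint8_t> out;
  uint32_t bitbuf = 0;
  int nbits = 0;
  void put(uint32_t value, int n) { // LSB-first
    bitbuf |= (value << nbits);
    nbits += n;
    while (nbits >= 8) {
      out.push_back((uint8_t) (bitbuf & 0xFF));
      bitbuf >>= 8;
      nbits -= 8;
    }
  }
  void put_huff(uint32_t code, int len) { // MSB of code first
    uint32_t rev = 0;
    for (int i = 0; i < len; ++i) rev |= ((code >> i) & 1u) << (len - 1 - i);
    put(rev, len);
  }
  void align() { if (nbits > 0) { out.push_back((uint8_t)(bitbuf & 0xFF)); bitbuf = 0; nbits = 0; } }
  size_t bit_length() const { return out.size() * 8 + nbits; }
};

// -------------------------------------------------------------- bit reader

struct BitReader {
  const uint8_t* buf;
  size_t len, pos = 0;
  uint32_t bitbuf = 0;
  int nbits = 0;
  BitReader(const uint8_t* b, size_t l) : buf(b), len(l) {}
  int get(int n) { // LSB-first; -1 on exhaustion
    while (nbits < n) {
      if (pos >= len) return -1;
      bitbuf |= ((uint32_t) buf[pos++]) << nbits;
      nbits += 8;
    }
    int v = (int) (bitbuf & ((1u << n) - 1));
    bitbuf >>= n;
    nbits -= n;
    return v;
  }
  void align() { bitbuf = 0; nbits = 0; }
};

// --------------------------------------------------- byte-alphabet Huffman

// [[Rcpp::export]]
List cpp_huffman_encode(RawVector data, IntegerVector lengths) {
  if (lengths.size() != 256) stop("invalid-input: lengths must have 256 entries");
  std::vector<int> len(lengths.begin(), lengths.end());
  std::vector<uint32_t> code;
  canonical_codes(len, code);
  BitWriter bw;
  for (R_xlen_t i = 0; i < data.size(); ++i) {
    int s = data[i];
    if (len[s] == 0) stop("invalid-input: symbol %d has no code", s);
    bw.put_huff(code[s], len[s]);
  }
  double nb = (double) bw.bit_length();
  bw.align();
  return List::create(_["payload"] = RawVector(bw.out.begin(), bw.out.end()),
                      _["n_bits"] = nb);
}

// canonical decoding tables: count[l], symbols sorted by (len, symbol)
struct HuffDec {
  std::vector<int> count;   // codes per length, index 1..maxlen
  std::vector<int> symbol;  // symbols in canonical order
  int maxlen;
};

static bool build_decoder(const std::vector<int>& len, HuffDec& hd,
                          bool* oversubscribed) {
  int maxlen = 0;
  for (int l : len) maxlen = std::max(maxlen, l);
  hd.maxlen = maxlen;
  hd.count.assign(maxlen + 1, 0);
  int nused = 0;
  for (int l : len) if (l > 0) { hd.count[l]++; nused++; }
  if (nused == 0) return false;
  // check for over-subscription
  long long left = 1;
  for (int l = 1; l <= maxlen; ++l) {
    left <<= 1;
    left -= hd.count[l];
    if (left < 0) { if (oversubscribed) *oversubscribed = true; return false; }
  }
  std::vector<int> offs(maxlen + 2, 0);
  for (int l = 1; l <= maxlen; ++l) offs[l + 1] = offs[l] + hd.count[l];
  hd.symbol.assign(nused, 0);
  for (int s = 0; s < (int) len.size(); ++s)
    if (len[s] > 0) hd.symbol[offs[len[s]]++] = s;
  return true;
}

static int decode_symbol(BitReader& br, const HuffDec& hd) {
  int code = 0, first = 0, index = 0;
  for (int l = 1; l <= hd.maxlen; ++l) {
    int b = br.get(1);
    if (b < 0) return -1; // truncated
    code |= b;
    int cnt = hd.count[l];
    if (code - first < cnt) return hd.symbol[index + (code - first)];
    index += cnt;
    first = (first + cnt) << 1;
    code <<= 1;
  }
  return -2; // invalid code
}

// [[Rcpp::export]]
RawVector cpp_huffman_decode(RawVector payload, double n_bits,
                             IntegerVector lengths, double n_out) {
  if (lengths.size() != 256) stop("invalid-input: lengths must have 256 entries");
  std::vector<int> len(lengths.begin(), lengths.end());
  HuffDec hd;
  bool over = false;
  if (!build_decoder(len, hd, &over)) {
    if (over) stop("corrupt-stream: over-subscribed Huffman code");
    if (n_out > 0) stop("corrupt-stream: empty code table with nonempty output");
    return RawVector(0);
  }
  BitReader br(RAW(payload), payload.size());
  size_t want = (size_t) n_out;
  std::vector<uint8_t> out;
  out.reserve(want);
  size_t used_bits = 0;
  while (out.size() < want) {
    int s = decode_symbol(br, hd);
    if (s < 0) stop("corrupt-stream: truncated or invalid Huffman bitstream");
    out.push_back((uint8_t) s);
    (void) used_bits;
  }
  // total consumed bits must not exceed declared bit length
  if ((double) (br.pos * 8 - br.nbits) > n_bits + 7)
    stop("corrupt-stream: bitstream overrun");
  return RawVector(out.begin(), out.end());
}

// ------------------------------------------------------------------- LZ77

static const int MIN_MATCH = 3, MAX_MATCH = 258, WINDOW = 32768;
static const int HASH_BITS = 15, HASH_SIZE = 1 << HASH_BITS;
static const int MAX_CHAIN = 256;

static inline int hash3(const uint8_t* p) {
  uint32_t h = ((uint32_t)p[0] << 16) | ((uint32_t)p[1] << 8) | p[2];
  return (int) ((h * 2654435761u) >> (32 - HASH_BITS));
}

// tokens appended as: tag (0 literal / 1 match), lit, len, dist
struct TokenSink {
  std::vector<uint8_t> tag;
  std::vector<uint8_t> lit;
  std::vector<int> len;
  std::vector<int> dist;
};

static void lz77_run(const uint8_t* data, size_t n, TokenSink& ts) {
  std::vector<int> head(HASH_SIZE, -1);
  std::vector<int> prev(n > 0 ? n : 1, -1);
  size_t i = 0;
  while (i < n) {
    int best_len = 0, best_dist = 0;
    if (i + MIN_MATCH <= n) {
      int h = hash3(data + i);
      int cand = head[h];
      int chain = 0;
      while (cand >= 0 && (size_t)(i - cand) <= (size_t)WINDOW &&
             chain < MAX_CHAIN) {
        int maxl = (int) std::min((size_t) MAX_MATCH, n - i);
        int l = 0;
        const uint8_t* a = data + cand;
        const uint8_t* b = data + i;
        while (l < maxl && a[l] == b[l]) ++l;
        if (l > best_len) { best_len = l; best_dist = (int)(i - cand); if (l == maxl) break; }
        cand = prev[cand];
        ++chain;
      }
    }
    if (best_len >= MIN_MATCH) {
      ts.tag.push_back(1);
      ts.lit.push_back(0);
      ts.len.push_back(best_len);
      ts.dist.push_back(best_dist);
      size_t stop_at = i + best_len;
      while (i < stop_at) {
        if (i + MIN_MATCH <= n) {
          int h = hash3(data + i);
          prev[i] = head[h];
          head[h] = (int) i;
        }
        ++i;
      }
    } else {
      ts.tag.push_back(0);
      ts.lit.push_back(data[i]);
      ts.len.push_back(0);
      ts.dist.push_back(0);
      if (i + MIN_MATCH <= n) {
        int h = hash3(data + i);
        prev[i] = head[h];
        head[h] = (int) i;
      }
      ++i;
    }
  }
}

// [[Rcpp::export]]
List cpp_lz77_tokenize(RawVector data) {
  TokenSink ts;
  lz77_run(RAW(data), data.size(), ts);
  int m = (int) ts.tag.size();
  IntegerVector tag(m), len(m), dist(m);
  RawVector lit(m);
  for (int k = 0; k < m; ++k) {
    tag[k] = ts.tag[k]; lit[k] = ts.lit[k];
    len[k] = ts.len[k]; dist[k] = ts.dist[k];
  }
  return List::create(_["tag"] = tag, _["literal"] = lit,
                      _["length"] = len, _["distance"] = dist);
}

// [[Rcpp::export]]
RawVector cpp_lz77_detokenize(IntegerVector tag, RawVector lit,
                              IntegerVector len, IntegerVector dist) {
  std::vector<uint8_t> out;
  int m = tag.size();
  for (int k = 0; k < m; ++k) {
    if (tag[k] == 0) {
      out.push_back(lit[k]);
    } else {
      int l = len[k], d = dist[k];
      if (d < 1 || (size_t) d > out.size())
        stop("corrupt-stream: match distance beyond output start");
      if (l < MIN_MATCH || l > MAX_MATCH)
        stop("corrupt-stream: match length out of range");
      size_t from = out.size() - d;
      for (int j = 0; j < l; ++j) out.push_back(out[from + j]); // overlap OK
    }
  }
  return RawVector(out.begin(), out.end());
}

// ------------------------------------------------------- DEFLATE constants

static const int LEN_BASE[29] = {3,4,5,6,7,8,9,10,11,13,15,17,19,23,27,31,35,43,
  51,59,67,83,99,115,131,163,195,227,258};
static const int LEN_EXTRA[29] = {0,0,0,0,0,0,0,0,1,1,1,1,2,2,2,2,3,3,3,3,4,4,
  4,4,5,5,5,5,0};
static const int DIST_BASE[30] = {1,2,3,4,5,7,9,13,17,25,33,49,65,97,129,193,
  257,385,513,769,1025,1537,2049,3073,4097,6145,8193,12289,16385,24577};
static const int DIST_EXTRA[30] = {0,0,0,0,1,1,2,2,3,3,4,4,5,5,6,6,7,7,8,8,9,9,
  10,10,11,11,12,12,13,13};
static const int CLC_ORDER[19] = {16,17,18,0,8,7,9,6,10,5,11,4,12,3,13,2,14,1,15};

static int length_code(int l) {
  for (int c = 28; c >= 0; --c) if (l >= LEN_BASE[c]) return c;
  return 0;
}
static int dist_code(int d) {
  for (int c = 29; c >= 0; --c) if (d >= DIST_BASE[c]) return c;
  return 0;
}

// -------------------------------------------------------- DEFLATE encoder

// run-length code the concatenated code-length sequence with symbols 16/17/18
static void rle_code_lengths(const std::vector<int>& seq,
                             std::vector<std::pair<int,int> >& out) {
  size_t i = 0, n = seq.size();
  int prevlen = -1;
  while (i < n) {
    int v = seq[i];
    size_t run = 1;
    while (i + run < n && seq[i + run] == v) ++run;
    if (v == 0) {
      size_t r = run;
      while (r >= 11) { size_t take = std::min(r, (size_t)138); out.push_back(std::make_pair(18, (int)take - 11)); r -= take; }
      if (r >= 3) { out.push_back(std::make_pair(17, (int)r - 3)); r = 0; }
      while (r-- > 0) out.push_back(std::make_pair(0, -1));
    } else {
      size_t r = run;
      if (v != prevlen) { out.push_back(std::make_pair(v, -1)); --r; }
      while (r >= 3) { size_t take = std::min(r, (size_t)6); out.push_back(std::make_pair(16, (int)take - 3)); r -= take; }
      while (r-- > 0) out.push_back(std::make_pair(v, -1));
    }
    prevlen = v;
    i += run;
  }
}

static void emit_stored(const uint8_t* data, size_t n, BitWriter& bw) {
  size_t pos = 0;
  do {
    size_t chunk = std::min(n - pos, (size_t) 65535);
    int final = (pos + chunk == n) ? 1 : 0;
    bw.put(final, 1);
    bw.put(0, 2);
    bw.align();
    bw.out.push_back((uint8_t)(chunk & 0xFF));
    bw.out.push_back((uint8_t)(chunk >> 8));
    bw.out.push_back((uint8_t)(~chunk & 0xFF));
    bw.out.push_back((uint8_t)((~chunk >> 8) & 0xFF));
    bw.out.insert(bw.out.end(), data + pos, data + pos + chunk);
    pos += chunk;
  } while (pos < n);
}

// [[Rcpp::export]]
RawVector cpp_deflate(RawVector data) {
  size_t n = data.size();
  const uint8_t* buf = RAW(data);

  if (n == 0) {
    BitWriter bw;
    emit_stored(buf, 0, bw);
    return RawVector(bw.out.begin(), bw.out.end());
  }

  TokenSink ts;
  lz77_run(buf, n, ts);
  size_t m = ts.tag.size();

  // symbol frequencies (litlen includes EOB = 256)
  std::vector<double> lfreq(286, 0.0), dfreq(30, 0.0);
  for (size_t k = 0; k < m; ++k) {
    if (ts.tag[k] == 0) lfreq[ts.lit[k]] += 1;
    else {
      lfreq[257 + length_code(ts.len[k])] += 1;
      dfreq[dist_code(ts.dist[k])] += 1;
    }
  }
  lfreq[256] += 1;

  std::vector<int> llen = huffman_lengths(lfreq, 15);
  bool any_dist = false;
  for (double f : dfreq) if (f > 0) { any_dist = true; break; }
  if (!any_dist) dfreq[0] = 1; // decodable placeholder distance code
  std::vector<int> dlen = huffman_lengths(dfreq, 15);

  int hlit = 286;  while (hlit > 257 && llen[hlit - 1] == 0) --hlit;
  int hdist = 30;  while (hdist > 1 && dlen[hdist - 1] == 0) --hdist;

  std::vector<int> clseq;
  clseq.insert(clseq.end(), llen.begin(), llen.begin() + hlit);
  clseq.insert(clseq.end(), dlen.begin(), dlen.begin() + hdist);
  std::vector<std::pair<int,int> > clrle;
  rle_code_lengths(clseq, clrle);

  std::vector<double> cfreq(19, 0.0);
  for (size_t k = 0; k < clrle.size(); ++k) cfreq[clrle[k].first] += 1;
  std::vector<int> clen = huffman_lengths(cfreq, 7);

  int hclen = 19;
  while (hclen > 4 && clen[CLC_ORDER[hclen - 1]] == 0) --hclen;

  std::vector<uint32_t> lcode, dcode, ccode;
  canonical_codes(llen, lcode);
  canonical_codes(dlen, dcode);
  canonical_codes(clen, ccode);

  BitWriter bw;
  bw.put(1, 1);      // BFINAL
  bw.put(2, 2);      // BTYPE = dynamic
  bw.put(hlit - 257, 5);
  bw.put(hdist - 1, 5);
  bw.put(hclen - 4, 4);
  for (int k = 0; k < hclen; ++k) bw.put(clen[CLC_ORDER[k]], 3);
  for (size_t k = 0; k < clrle.size(); ++k) {
    int sym = clrle[k].first, extra = clrle[k].second;
    bw.put_huff(ccode[sym], clen[sym]);
    if (sym == 16) bw.put(extra, 2);
    else if (sym == 17) bw.put(extra, 3);
    else if (sym == 18) bw.put(extra, 7);
  }
  for (size_t k = 0; k < m; ++k) {
    if (ts.tag[k] == 0) {
      int s = ts.lit[k];
      bw.put_huff(lcode[s], llen[s]);
    } else {
      int lc = length_code(ts.len[k]);
      bw.put_huff(lcode[257 + lc], llen[257 + lc]);
      if (LEN_EXTRA[lc] > 0) bw.put(ts.len[k] - LEN_BASE[lc], LEN_EXTRA[lc]);
      int dc = dist_code(ts.dist[k]);
      bw.put_huff(dcode[dc], dlen[dc]);
      if (DIST_EXTRA[dc] > 0) bw.put(ts.dist[k] - DIST_BASE[dc], DIST_EXTRA[dc]);
    }
  }
  bw.put_huff(lcode[256], llen[256]); // end of block
  size_t dynamic_bits = bw.bit_length();
  bw.align();

  // stored fallback if the dynamic block expanded the data
  size_t stored_bytes = n + 5 * ((n + 65534) / 65535);
  if ((dynamic_bits + 7) / 8 > stored_bytes) {
    BitWriter sw;
    emit_stored(buf, n, sw);
    return RawVector(sw.out.begin(), sw.out.end());
  }
  return RawVector(bw.out.begin(), bw.out.end());
}

// -------------------------------------------------------- DEFLATE decoder

static void inflate_block_data(BitReader& br, const HuffDec& lt,
                               const HuffDec& dt, bool have_dist,
                               std::vector<uint8_t>& out) {
  for (;;) {
    int sym = decode_symbol(br, lt);
    if (sym == -1) stop("corrupt-stream: truncated stream");
    if (sym == -2) stop("corrupt-stream: invalid literal/length code");
    if (sym < 256) {
      out.push_back((uint8_t) sym);
    } else if (sym == 256) {
      return;
    } else {
      if (sym > 285) stop("corrupt-stream: invalid length symbol");
      int lc = sym - 257;
      int extra = LEN_EXTRA[lc];
      int ev = extra ? br.get(extra) : 0;
      if (ev < 0) stop("corrupt-stream: truncated stream");
      int length = LEN_BASE[lc] + ev;
      if (!have_dist) stop("corrupt-stream: match with no distance code");
      int dsym = decode_symbol(br, dt);
      if (dsym == -1) stop("corrupt-stream: truncated stream");
      if (dsym == -2) stop("corrupt-stream: invalid distance code");
      if (dsym > 29) stop("corrupt-stream: invalid distance symbol");
      int dextra = DIST_EXTRA[dsym];
      int dev = dextra ? br.get(dextra) : 0;
      if (dev < 0) stop("corrupt-stream: truncated stream");
      int dist = DIST_BASE[dsym] + dev;
      if ((size_t) dist > out.size())
        stop("corrupt-stream: distance beyond output start");
      size_t from = out.size() - dist;
      for (int j = 0; j < length; ++j) out.push_back(out[from + j]);
    }
  }
}

// [[Rcpp::export]]
RawVector cpp_inflate(RawVector stream) {
  BitReader br(RAW(stream), stream.size());
  std::vector<uint8_t> out;
  int bfinal = 0;
  do {
    bfinal = br.get(1);
    int btype = br.get(2);
    if (bfinal < 0 || btype < 0) stop("corrupt-stream: truncated block header");
    if (btype == 0) { // stored
      br.align();
      if (br.pos + 4 > br.len) stop("corrupt-stream: truncated stored header");
      unsigned len = br.buf[br.pos] | (br.buf[br.pos + 1] << 8);
      unsigned nlen = br.buf[br.pos + 2] | (br.buf[br.pos + 3] << 8);
      br.pos += 4;
      if ((len ^ nlen) != 0xFFFFu) stop("corrupt-stream: stored LEN/NLEN mismatch");
      if (br.pos + len > br.len) stop("corrupt-stream: truncated stored data");
      out.insert(out.end(), br.buf + br.pos, br.buf + br.pos + len);
      br.pos += len;
    } else if (btype == 1) { // fixed Huffman
      std::vector<int> llen(288), dlen(30, 5);
      for (int s = 0; s < 144; ++s) llen[s] = 8;
      for (int s = 144; s < 256; ++s) llen[s] = 9;
      for (int s = 256; s < 280; ++s) llen[s] = 7;
      for (int s = 280; s < 288; ++s) llen[s] = 8;
      HuffDec lt, dt;
      build_decoder(llen, lt, NULL);
      build_decoder(dlen, dt, NULL);
      inflate_block_data(br, lt, dt, true, out);
    } else if (btype == 2) { // dynamic Huffman
      int hlit = br.get(5), hdist = br.get(5), hclen = br.get(4);
      if (hlit < 0 || hdist < 0 || hclen < 0)
        stop("corrupt-stream: truncated dynamic header");
      hlit += 257; hdist += 1; hclen += 4;
      if (hlit > 286) stop("corrupt-stream: too many literal/length codes");
      std::vector<int> clen(19, 0);
      for (int k = 0; k < hclen; ++k) {
        int v = br.get(3);
        if (v < 0) stop("corrupt-stream: truncated code-length codes");
        clen[CLC_ORDER[k]] = v;
      }
      HuffDec ct;
      bool over = false;
      if (!build_decoder(clen, ct, &over))
        stop(over ? "corrupt-stream: over-subscribed code-length code"
                  : "corrupt-stream: empty code-length code");
      std::vector<int> lens;
      lens.reserve(hlit + hdist);
      while ((int) lens.size() < hlit + hdist) {
        int sym = decode_symbol(br, ct);
        if (sym == -1) stop("corrupt-stream: truncated stream");
        if (sym == -2) stop("corrupt-stream: invalid code-length symbol");
        if (sym < 16) lens.push_back(sym);
        else if (sym == 16) {
          if (lens.empty()) stop("corrupt-stream: repeat with no previous length");
          int r = br.get(2);
          if (r < 0) stop("corrupt-stream: truncated stream");
          int v = lens.back();
          for (int j = 0; j < r + 3; ++j) lens.push_back(v);
        } else if (sym == 17) {
          int r = br.get(3);
          if (r < 0) stop("corrupt-stream: truncated stream");
          for (int j = 0; j < r + 3; ++j) lens.push_back(0);
        } else {
          int r = br.get(7);
          if (r < 0) stop("corrupt-stream: truncated stream");
          for (int j = 0; j < r + 11; ++j) lens.push_back(0);
        }
      }
      if ((int) lens.size() != hlit + hdist)
        stop("corrupt-stream: code-length sequence overrun");
      std::vector<int> llen(lens.begin(), lens.begin() + hlit);
      std::vector<int> dlen(lens.begin() + hlit, lens.end());
      if (llen[256] == 0) stop("corrupt-stream: missing end-of-block code");
      HuffDec lt, dt;
      over = false;
      if (!build_decoder(llen, lt, &over))
        stop(over ? "corrupt-stream: over-subscribed literal/length code"
                  : "corrupt-stream: empty literal/length code");
      over = false;
      bool have_dist = build_decoder(dlen, dt, &over);
      if (over) stop("corrupt-stream: over-subscribed distance code");
      inflate_block_data(br, lt, dt, have_dist, out);
    } else {
      stop("corrupt-stream: invalid block type");
    }
  } while (!bfinal);
  return RawVector(out.begin(), out.end());
}
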