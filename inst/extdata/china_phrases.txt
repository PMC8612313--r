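信息
視頻
軟件
網絡
屏幕
打印
智能手機
土豆
出租車
公交車
幼兒園
疫苗接種點
衛健委
國家衛健委
小區
本土病例
核酸檢測
方艙
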