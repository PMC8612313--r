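的
了
是
在
我
有
和
就
不
人
都
一
一個
上
也
很
到
說
要
去
你
會
著
沒有
看
好
自己
這
那
他
她
它
我們
你們
他們
與
及
或
而
被
把
讓
向
從
對
於
之
以
為
因為
所以
但是
如果
還
又
再
得
地
啊
吧
嗎
呢
個
些
此
其
並
等
但
卻
只
請
大家
一起
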