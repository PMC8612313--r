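simplified	traditional
医	醫
发	發
汉	漢
华	華
国	國
当	當
从	從
众	眾
优	優
会	會
伟	偉
传	傳
体	體
关	關
东	東
车	車
长	長
马	馬
鸟	鳥
龙	龍
学	學
无	無
门	門
风	風
园	園
圆	圓
远	遠
运	運
过	過
还	還
这	這
边	邊
进	進
问	問
间	間
闻	聞
们	們
级	級
红	紅
绿	綠
纸	紙
线	線
组	組
经	經
给	給
结	結
统	統
继	繼
维	維
网	網
罗	羅
买	買
卖	賣
读	讀
说	說
请	請
谢	謝
谁	誰
话	話
语	語
误	誤
讯	訊
议	議
记	記
计	計
论	論
识	識
证	證
词	詞
译	譯
试	試
该	該
详	詳
贝	貝
员	員
财	財
货	貨
质	質
购	購
贵	貴
费	費
资	資
赛	賽
钟	鐘
钱	錢
铁	鐵
银	銀
错	錯
锁	鎖
镇	鎮
阳	陽
阴	陰
际	際
陈	陳
险	險
隐	隱
难	難
韦	韋
页	頁
顶	頂
顺	順
须	須
顾	顧
顿	頓
预	預
领	領
频	頻
题	題
颜	顏
饭	飯
饮	飲
饱	飽
饿	餓
馆	館
驾	駕
验	驗
骂	罵
骗	騙
鱼	魚
鲜	鮮
鸡	雞
鸭	鴨
麦	麥
黄	黃
齐	齊
齿	齒
严	嚴
丧	喪
个	個
临	臨
为	為
举	舉
义	義
乐	樂
习	習
书	書
买	買
乱	亂
争	爭
亏	虧
亿	億
仅	僅
侧	側
侨	僑
俭	儉
债	債
倾	傾
兑	兌
兰	蘭
养	養
兽	獸
冲	衝
决	決
况	況
冻	凍
净	淨
准	準
减	減
剂	劑
剧	劇
劝	勸
办	辦
务	務
动	動
励	勵
劳	勞
势	勢
匮	匱
区	區
协	協
单	單
卫	衛
厂	廠
厅	廳
历	歷
厕	廁
县	縣
双	雙
变	變
叠	疊
号	號
叹	嘆
吓	嚇
吗	嗎
吨	噸
听	聽
启	啟
呜	嗚
咏	詠
响	響
哑	啞
唤	喚
啸	嘯
喷	噴
团	團
围	圍
图	圖
圣	聖
场	場
块	塊
坚	堅
坏	壞
垒	壘
垦	墾
压	壓
垄	壟
壮	壯
声	聲
壶	壺
处	處
备	備
复	復
够	夠
头	頭
夹	夾
夺	奪
奋	奮
妆	妝
妇	婦
妈	媽
姗	姍
娄	婁
娱	娛
婶	嬸
嫒	嬡
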